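# packaged calibration table: 6x6 metallic microneedle array
# FEM-derived inter-sheet current interval division (uA), one column set per
# sheet-pair distance (AB, AC, AD, AE, AF); with six tips per sheet the
# states are grouped, so each interval maps to a set of transdermal states
# transcribed verbatim from the printed device characterisation
pair,distance,interval,states,lower_uA,upper_uA,length_uA
AB,1,1,0-0,725,,
AB,1,2,0-1;1-1,633,725,91
AB,1,3,0-2;1-2,556,633,77
AB,1,4,0-3;2-2;1-3;2-3,436,556,118
AB,1,5,0-4;3-3;1-4;2-4;3-4;4-4,270,436,166
AB,1,6,0-5;1-5;2-5;3-5;4-5;5-5,95,270,174
AB,1,7,6+,0,95,95
AC,2,1,0-0,562,,
AC,2,2,0-1;1-1,506,562,56
AC,2,3,0-2;1-2,455,506,50
AC,2,4,0-3;2-2;1-3;2-3,373,455,82
AC,2,5,0-4;3-3;1-4;2-4;3-4;4-4,245,373,127
AC,2,6,0-5;1-5;2-5;3-5;4-5;5-5,92,245,152
AC,2,7,6+,0,92,91
AD,3,1,0-0,486,,
AD,3,2,0-1;1-1,443,486,42
AD,3,3,0-2;1-2,403,443,39
AD,3,4,0-3;2-2;1-3;2-3,337,403,66
AD,3,5,0-4;3-3;1-4;2-4;3-4;4-4,229,337,108
AD,3,6,0-5;1-5;2-5;3-5;4-5;5-5,89,229,140
AD,3,7,6+,0,89,88
AE,4,1,0-0,436,,
AE,4,2,0-1;1-1,401,436,34
AE,4,3,0-2;1-2,369,401,32
AE,4,4,0-3;2-2;1-3;2-3,312,369,56
AE,4,5,0-4;3-3;1-4;2-4;3-4;4-4,217,312,95
AE,4,6,0-5;1-5;2-5;3-5;4-5;5-5,86,217,130
AE,4,7,6+,0,86,86
AF,5,1,0-0,397,,
AF,5,2,0-1;1-1,368,397,29
AF,5,3,0-2;1-2,340,368,28
AF,5,4,0-3;2-2;1-3;2-3,291,340,49
AF,5,5,0-4;3-3;1-4;2-4;3-4;4-4,206,291,85
AF,5,6,0-5;1-5;2-5;3-5;4-5;5-5,84,206,122
AF,5,7,6+,0,84,84
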