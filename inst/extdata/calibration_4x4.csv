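# packaged calibration table: 4x4 metallic microneedle array
# FEM-derived inter-sheet current interval division (uA), one column set per
# sheet-pair distance (AB, AC, AD)
# transcribed verbatim from the printed device characterisation; the
# distance-2 interval 5 upper bound (394) is preserved as printed even
# though it contradicts the neighbouring rows
pair,distance,interval,states,lower_uA,upper_uA,length_uA
AB,1,1,0-0,484,,
AB,1,2,0-1,426,484,57
AB,1,3,1-1,382,426,44
AB,1,4,0-2,346,382,36
AB,1,5,1-2,304,346,42
AB,1,6,2-2,256,304,48
AB,1,7,0-3,226,256,30
AB,1,8,1-3,207,226,19
AB,1,9,2-3,172,207,34
AB,1,10,3-3,88,172,84
AB,1,11,4+,0,88,88
AC,2,1,0-0,387,,
AC,2,2,0-1,349,387,37
AC,2,3,1-1,319,349,30
AC,2,4,0-2,294,319,25
AC,2,5,1-2,263,394,31
AC,2,6,2-2,226,263,37
AC,2,7,0-3,203,226,24
AC,2,8,1-3,187,203,15
AC,2,9,2-3,159,187,29
AC,2,10,3-3,83,159,76
AC,2,11,4+,0,83,83
AD,3,1,0-0,341,,
AD,3,2,0-1,311,341,30
AD,3,3,1-1,287,311,24
AD,3,4,0-2,266,287,21
AD,3,5,1-2,240,266,26
AD,3,6,2-2,209,240,31
AD,3,7,0-3,189,209,20
AD,3,8,1-3,176,189,13
AD,3,9,2-3,150,176,26
AD,3,10,3-3,80,150,70
AD,3,11,4+,0,80,80
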