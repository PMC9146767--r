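# packaged calibration table: 3x3 metallic microneedle array
# FEM-derived inter-sheet current interval division (uA), one column set per
# sheet-pair distance (AB = adjacent sheets, AC = two pitches apart)
# transcribed verbatim from the printed device characterisation; the
# distance-1 interval 5/6 overlap (171-177 uA) and the length entries that
# disagree with the printed bounds are preserved as printed
pair,distance,interval,states,lower_uA,upper_uA,length_uA
AB,1,1,0-0,360,,
AB,1,2,0-1,301,360,59
AB,1,3,1-1,246,301,55
AB,1,4,0-2,204,246,42
AB,1,5,1-2,171,204,34
AB,1,6,2-2,83,177,87
AB,1,7,3+,0,83,65
AC,2,1,0-0,289,,
AC,2,2,0-1,250,289,39
AC,2,3,1-1,210,250,39
AC,2,4,0-2,179,210,31
AC,2,5,1-2,152,179,27
AC,2,6,2-2,76,152,76
AC,2,7,3+,0,76,58
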