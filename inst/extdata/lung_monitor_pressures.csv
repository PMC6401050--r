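# Simulated lung-surface pressures (Pa) at the 6 monitor points, both lung
# sides, 5 standoffs. Transcribed from the published monitor table; each
# block is annotated with the Pearson r (vs the Smith scores fixture) that
# verifies the transcription against the published correlation table.
group,side,point_name,pressure_pa
# (40 cm, L): reproduces published r = 0.899
40,L,apex_pulmonis,1110
40,L,middle_lateral,1297
40,L,lower_lateral,1350
40,L,lower_interior,2322
40,L,lower_anterior,438
40,L,interior,2751
# (40 cm, R): reproduces published r = 0.891
40,R,apex_pulmonis,928
40,R,middle_lateral,1374
40,R,lower_lateral,1365
40,R,lower_interior,2916
40,R,lower_anterior,736
40,R,interior,2240
# (50 cm, L): reproduces published r = 0.949
50,L,apex_pulmonis,795
50,L,middle_lateral,949
50,L,lower_lateral,1049
50,L,lower_interior,1924
50,L,lower_anterior,289
50,L,interior,2009
# (50 cm, R): reproduces published r = 0.908
50,R,apex_pulmonis,733
50,R,middle_lateral,1023
50,R,lower_lateral,1056
50,R,lower_interior,2254
50,R,lower_anterior,512
50,R,interior,1565
# (60 cm, L): reproduces published r = 0.939
60,L,apex_pulmonis,598
60,L,middle_lateral,673
60,L,lower_lateral,715
60,L,lower_interior,950
60,L,lower_anterior,204
60,L,interior,1466
# (60 cm, R): reproduces published r = 0.947
60,R,apex_pulmonis,488
60,R,middle_lateral,765
60,R,lower_lateral,725
60,R,lower_interior,1236
60,R,lower_anterior,355
60,R,interior,1177
# (70 cm, L): reproduces published r = 0.604
70,L,apex_pulmonis,437
70,L,middle_lateral,511
70,L,lower_lateral,529
70,L,lower_interior,933
70,L,lower_anterior,168
70,L,interior,1026
# (70 cm, R): reproduces published r = 0.783
70,R,apex_pulmonis,357
70,R,middle_lateral,566
70,R,lower_lateral,568
70,R,lower_interior,1189
70,R,lower_anterior,305
70,R,interior,922
# (80 cm, L): reproduces published r = 0.498
80,L,apex_pulmonis,379
80,L,middle_lateral,409
80,L,lower_lateral,309
80,L,lower_interior,668
80,L,lower_anterior,141
80,L,interior,982
# (80 cm, R): reproduces published r = 0.912
80,R,apex_pulmonis,314
80,R,middle_lateral,480
80,R,lower_lateral,478
80,R,lower_interior,992
80,R,lower_anterior,244
80,R,interior,756
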