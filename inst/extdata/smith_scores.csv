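# Averaged total Smith pathology scores (0-12) at the 6 biopsy points, both
# lung sides: 5 injured groups (standoff in cm) and the untreated group.
# Transcribed from the published score table; injured blocks are annotated
# with the Pearson r / paired-t p they reproduce. Note: the published text
# also quotes r = 0.941 for (60, R) where the table prints 0.947; this
# transcription reproduces 0.947. The published Pearson significance 0.605
# for (70, R) recomputes as 0.065 from r = 0.783, n = 6.
group,side,point_name,score
# (40 cm, L): reproduces published r = 0.899, paired-t p = 0.001
40,L,apex_pulmonis,5
40,L,middle_lateral,6.8
40,L,lower_lateral,10
40,L,lower_interior,12
40,L,lower_anterior,4.6
40,L,interior,11.8
# (40 cm, R): reproduces published r = 0.891, paired-t p = 0.001
40,R,apex_pulmonis,4.4
40,R,middle_lateral,6.2
40,R,lower_lateral,9
40,R,lower_interior,11.6
40,R,lower_anterior,6
40,R,interior,9.2
# (50 cm, L): reproduces published r = 0.949, paired-t p = 0.002
50,L,apex_pulmonis,3.4
50,L,middle_lateral,4.6
50,L,lower_lateral,6.6
50,L,lower_interior,8.4
50,L,lower_anterior,3.2
50,L,interior,9
# (50 cm, R): reproduces published r = 0.908, paired-t p = 0.007
50,R,apex_pulmonis,2
50,R,middle_lateral,3.4
50,R,lower_lateral,5.6
50,R,lower_interior,8.2
50,R,lower_anterior,2.2
50,R,interior,8
# (60 cm, L): reproduces published r = 0.939, paired-t p = 0.009
60,L,apex_pulmonis,2
60,L,middle_lateral,2.2
60,L,lower_lateral,3.8
60,L,lower_interior,5.4
60,L,lower_anterior,1.6
60,L,interior,7.4
# (60 cm, R): reproduces published r = 0.947, paired-t p = 0.002
60,R,apex_pulmonis,1.4
60,R,middle_lateral,3.4
60,R,lower_lateral,3.6
60,R,lower_interior,4.8
60,R,lower_anterior,2
60,R,interior,5
# (70 cm, L): reproduces published r = 0.604, paired-t p = 0.001
70,L,apex_pulmonis,1.2
70,L,middle_lateral,1.8
70,L,lower_lateral,2.4
70,L,lower_interior,3.8
70,L,lower_anterior,2.6
70,L,interior,3
# (70 cm, R): reproduces published r = 0.783, paired-t p = 0.001
70,R,apex_pulmonis,0.8
70,R,middle_lateral,2
70,R,lower_lateral,1.4
70,R,lower_interior,2.6
70,R,lower_anterior,1.8
70,R,interior,3
# (80 cm, L): reproduces published r = 0.498, paired-t p = 0.111
80,L,apex_pulmonis,0
80,L,middle_lateral,0.2
80,L,lower_lateral,0.2
80,L,lower_interior,0.6
80,L,lower_anterior,0
80,L,interior,0.2
# (80 cm, R): reproduces published r = 0.912, paired-t p = 0.809
80,R,apex_pulmonis,0
80,R,middle_lateral,0
80,R,lower_lateral,0
80,R,lower_interior,0.6
80,R,lower_anterior,0
80,R,interior,0.2
# untreated L baseline
untreated,L,apex_pulmonis,0
untreated,L,middle_lateral,0
untreated,L,lower_lateral,0.1
untreated,L,lower_interior,0.3
untreated,L,lower_anterior,0
untreated,L,interior,0.2
# untreated R baseline
untreated,R,apex_pulmonis,0
untreated,R,middle_lateral,0.2
untreated,R,lower_lateral,0
untreated,R,lower_interior,0.3
untreated,R,lower_anterior,0
untreated,R,interior,0.2
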