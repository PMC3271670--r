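# Recombination rules for the DCJ-substitution distance.
# table 1: recombinations of two labeled paths with delta_d <= -1
#          (sources; one witness resultant pair; per-path score).
# table 2: recombinations with delta_d = 0 whose resultants include a
#          source type of table 1.
# table 3: the greedy recombination groups U..Z with their source
#          multisets, total delta_d, and score = delta_d per source path.
# Path classes: kind AA/BB/AB, ':', run structure: 'e' (clean), or first
# run genome + run count mod 4 (E = either reading direction).
# Generated from the operation engine; validated against it at load time.
table	group	source1	source2	resultants	delta_sigma	delta_dcj	delta_d	score
1	X	AA:A1	BB:A1	AB:A1+AB:e	-1	0	-1	-0.5
1	X	AA:A1	BB:A3	AB:A3+AB:e	-1	0	-1	-0.5
1	X	AA:A1	BB:B1	AB:A2+AB:e	-1	0	-1	-0.5
1	X	AA:A1	BB:E2	AB:A2+AB:e	-1	0	-1	-0.5
1	X	AA:A1	BB:E4	AB:A4+AB:e	-1	0	-1	-0.5
1	X	AA:A3	BB:A1	AB:A3+AB:e	-1	0	-1	-0.5
1	X	AA:A3	BB:E4	AB:A2+AB:e	-1	0	-1	-0.5
1	X	AA:B1	BB:A1	AB:B2+AB:e	-1	0	-1	-0.5
1	X	AA:B1	BB:B1	AB:B1+AB:e	-1	0	-1	-0.5
1	X	AA:B1	BB:B3	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:B1	BB:E2	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:B1	BB:E4	AB:B4+AB:e	-1	0	-1	-0.5
1	X	AA:B3	BB:B1	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:B3	BB:E4	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:E2	BB:A1	AB:B2+AB:e	-1	0	-1	-0.5
1	X	AA:E2	BB:B1	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:E2	BB:E2	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:E2	BB:E4	AB:B1+AB:e	-1	0	-1	-0.5
1	X	AA:E4	AA:E4	AA:A3+AA:B3	-2	1	-1	-0.5
1	X	AA:E4	BB:A1	AB:B4+AB:e	-1	0	-1	-0.5
1	X	AA:E4	BB:A3	AB:B2+AB:e	-1	0	-1	-0.5
1	X	AA:E4	BB:B1	AB:A4+AB:e	-1	0	-1	-0.5
1	X	AA:E4	BB:B3	AB:B3+AB:e	-1	0	-1	-0.5
1	X	AA:E4	BB:E2	AB:B1+AB:e	-1	0	-1	-0.5
1	U	AA:E4	BB:E4	AB:B3+AB:e	-2	0	-2	-1
1	X	AA:E4	AB:A4	AA:A3+AB:B3	-2	1	-1	-0.5
1	X	AA:E4	AB:B4	AA:B3+AB:e	-2	1	-1	-0.5
1	X	BB:E4	BB:E4	BB:A3+BB:B3	-2	1	-1	-0.5
1	X	BB:E4	AB:A4	AB:e+BB:B3	-2	1	-1	-0.5
1	X	BB:E4	AB:B4	AB:B3+BB:A3	-2	1	-1	-0.5
1	X	AB:A4	AB:B4	AB:B3+AB:e	-2	1	-1	-0.5
2	T2	AB:A4	AB:A4	AA:A3+BB:B3	-2	2	0	0
2	T2	AB:A4	AB:A4	AA:e+BB:B3	-2	2	0	0
2	T2	AB:B4	AB:B4	AA:B3+BB:A3	-2	2	0	0
2	T2	AB:B4	AB:B4	AA:e+BB:A3	-2	2	0	0
2	T2	AA:A1	AB:B4	AA:E4+AB:e	-1	1	0	0
2	T2	AA:B1	AB:A4	AA:E4+AB:e	-1	1	0	0
2	T2	BB:A1	AB:A4	AB:e+BB:E4	-1	1	0	0
2	T2	BB:B1	AB:B4	AB:e+BB:E4	-1	1	0	0
2	T2	AA:B3	AB:A4	AA:A3+AB:B3	-1	1	0	0
2	T2	AA:B3	AB:A4	AA:E2+AB:e	-1	1	0	0
2	T2	AA:A3	AB:B4	AA:B3+AB:A3	-1	1	0	0
2	T2	AA:A3	AB:B4	AA:E2+AB:e	-1	1	0	0
2	T2	AA:E2	AB:A4	AA:A1+AB:B3	-1	1	0	0
2	T2	AA:E2	AB:B4	AA:B1+AB:e	-1	1	0	0
2	T2	BB:A3	AB:A4	AB:A3+BB:B3	-1	1	0	0
2	T2	BB:A3	AB:A4	AB:e+BB:E2	-1	1	0	0
2	T2	BB:B3	AB:B4	AB:B3+BB:A3	-1	1	0	0
2	T2	BB:B3	AB:B4	AB:e+BB:E2	-1	1	0	0
2	T2	BB:E2	AB:A4	AB:e+BB:B1	-1	1	0	0
2	T2	BB:E2	AB:B4	AB:B3+BB:A1	-1	1	0	0
2	T2	AA:A3	BB:E2	AB:A4+AB:e	0	0	0	0
2	T2	AA:B3	BB:E2	AB:B4+AB:e	0	0	0	0
2	T2	AA:E2	BB:A3	AB:B4+AB:e	0	0	0	0
2	T2	AA:E2	BB:B3	AB:A4+AB:e	0	0	0	0
2	T2	AA:A3	BB:B1	AB:A4+AB:e	0	0	0	0
2	T2	AA:B3	BB:A1	AB:B4+AB:e	0	0	0	0
2	T2	AA:A1	BB:B3	AB:A4+AB:e	0	0	0	0
2	T2	AA:B1	BB:A3	AB:B4+AB:e	0	0	0	0
3	U	AA:E4+BB:E4		2 sorted AB-paths	NA	NA	-2	-1
3	V	AA:E4+AA:E4+BB:A1+BB:B1		4 sorted AB-paths	NA	NA	-3	-0.75
3	V	BB:E4+BB:E4+AA:A1+AA:B1		4 sorted AB-paths	NA	NA	-3	-0.75
3	W	AA:E4+AA:E4+BB:A1		2 sorted AB-paths + AA:B3	NA	NA	-2	-0.667
3	W	AA:E4+AA:E4+BB:B1		2 sorted AB-paths + AA:A3	NA	NA	-2	-0.667
3	W	BB:E4+BB:E4+AA:A1		2 sorted AB-paths + BB:B3	NA	NA	-2	-0.667
3	W	BB:E4+BB:E4+AA:B1		2 sorted AB-paths + BB:A3	NA	NA	-2	-0.667
3	W	AA:E4+AB:A4+BB:A1		3 sorted AB-paths	NA	NA	-2	-0.667
3	W	AA:E4+AB:B4+BB:B1		3 sorted AB-paths	NA	NA	-2	-0.667
3	W	BB:E4+AB:A4+AA:B1		3 sorted AB-paths	NA	NA	-2	-0.667
3	W	BB:E4+AB:B4+AA:A1		3 sorted AB-paths	NA	NA	-2	-0.667
3	X	any remaining Table-1 pair with delta_d = -1		2 sorted AB-paths	NA	NA	-1	-0.5
3	Y	AB:A4+AB:A4+AA:B1+BB:A1		4 sorted AB-paths	NA	NA	-2	-0.5
3	Y	AB:B4+AB:B4+AA:A1+BB:B1		4 sorted AB-paths	NA	NA	-2	-0.5
3	Z	AB:A4+AB:A4+BB:A1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AB:A4+AB:A4+AA:B1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AB:B4+AB:B4+BB:B1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AB:B4+AB:B4+AA:A1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:A1+AB:B4+BB:B3		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:A3+AB:B4+BB:B1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:A3+AB:B4+BB:E2		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:B1+AB:A4+BB:A3		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:B3+AB:A4+BB:A1		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:B3+AB:A4+BB:E2		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:E2+AB:A4+BB:A3		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:E2+AB:B4+BB:B3		3 sorted AB-paths	NA	NA	-1	-0.333
3	Z	AA:A3+AA:B3+BB:E2+BB:E2		4 sorted AB-paths	NA	NA	-1	-0.25
3	Z	AA:E2+AA:E2+BB:A3+BB:B3		4 sorted AB-paths	NA	NA	-1	-0.25
3	Z	AA:A3+AB:B4+AB:B4+BB:B3		4 sorted AB-paths	NA	NA	-1	-0.25
3	Z	AA:B3+AB:A4+AB:A4+BB:A3		4 sorted AB-paths	NA	NA	-1	-0.25
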