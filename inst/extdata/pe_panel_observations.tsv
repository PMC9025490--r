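compound_id	observed_mz	count_group1	count_group2	count_group3	count_group4
HMDB0002282	366.05	1	2	0	2
HMDB0003689	399.25	3	3	0	1
HMDB0013327	412.25	2	2	0	0
HMDB0006766	503.1	1	2	0	0
HMDB0004220	574.1	0	2	0	0
HMDB0001445	610.15	1	2	1	3
HMDB0006557	612.05	0	2	0	0
HMDB0011764	618.6	1	3	1	2
HMDB0000381	622.15	3	2	1	3
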