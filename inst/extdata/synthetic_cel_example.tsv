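patient_id	month	cel	relapse
SYN01	1	3	0
SYN01	2	55	1
SYN01	3	6	0
SYN01	4	1	0
SYN01	5	1	0
SYN01	6	1	0
SYN01	7	5	1
SYN01	8	1	0
SYN01	9	2	0
SYN01	10	0	0
SYN01	11	0	0
SYN01	12	0	0
SYN01	13	0	0
SYN01	14	0	0
SYN01	15	0	0
SYN01	16	2	0
SYN01	17	0	0
SYN01	18	19	0
SYN01	19	1	0
SYN01	20	1	0
SYN01	21	2	0
SYN01	22	1	0
SYN01	23	2	0
SYN01	24	2	0
SYN02	1	2	0
SYN02	2	2	0
SYN02	3	1	0
SYN02	4	1	0
SYN02	5	1	0
SYN02	6	0	0
SYN02	7	0	0
SYN02	8	0	0
SYN02	9	0	0
SYN02	10	1	0
SYN02	11	0	0
SYN02	12	2	0
SYN02	13	5	0
SYN02	14	1	0
SYN02	15	0	0
SYN02	16	0	0
SYN02	17	1	0
SYN02	18	0	0
SYN02	19	1	0
SYN02	20	0	0
SYN02	21	1	0
SYN02	22	1	0
SYN02	23	0	0
SYN02	24	0	0
SYN03	1	0	0
SYN03	2	0	0
SYN03	3	0	0
SYN03	4	1	0
SYN03	5	0	0
SYN03	6	0	0
SYN03	7	0	0
SYN03	8	0	0
SYN03	9	0	0
SYN03	10	0	0
SYN03	11	0	0
SYN03	12	1	0
SYN03	13	0	0
SYN03	14	0	0
SYN03	15	6	0
SYN03	16	1	0
SYN03	17	0	0
SYN03	18	1	0
SYN03	19	2	0
SYN03	20	3	0
SYN03	21	0	0
SYN03	22	0	0
SYN03	23	0	0
SYN03	24	0	0
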