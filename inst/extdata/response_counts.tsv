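image_id	group	correct	incorrect	truth_affected
WS	clinician	17	5	TRUE
WS	nonclinician	13	9	TRUE
UNAFF1	clinician	22	0	FALSE
UNAFF1	nonclinician	19	3	FALSE
RSTS1	clinician	21	0	TRUE
RSTS1	nonclinician	21	1	TRUE
UNAFF2	clinician	19	3	FALSE
UNAFF2	nonclinician	14	8	FALSE
WHS	clinician	20	2	TRUE
WHS	nonclinician	19	3	TRUE
UNAFF3	clinician	22	0	FALSE
UNAFF3	nonclinician	20	2	FALSE
CdLS	clinician	22	0	TRUE
CdLS	nonclinician	22	0	TRUE
DS	clinician	22	0	TRUE
DS	nonclinician	21	1	TRUE
UNAFF4	clinician	15	6	FALSE
UNAFF4	nonclinician	15	6	FALSE
KS	clinician	19	3	TRUE
KS	nonclinician	13	9	TRUE
NS	clinician	21	0	TRUE
NS	nonclinician	21	0	TRUE
UNAFF5	clinician	18	4	FALSE
UNAFF5	nonclinician	18	4	FALSE
22q11DS	clinician	21	1	TRUE
22q11DS	nonclinician	19	3	TRUE
PWS	clinician	16	5	TRUE
PWS	nonclinician	10	12	TRUE
UNAFF6	clinician	14	8	FALSE
UNAFF6	nonclinician	19	3	FALSE
BWS	clinician	8	13	TRUE
BWS	nonclinician	5	17	TRUE
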