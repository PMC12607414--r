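Character	JXNU 21042801	JXNU 21042802	JXNU 21042803	JXNU 21042804	JXNU 21061505	JXNU 21061506	JXNU 21061507	JXNU 21061508	JXNU 21061509
Sex	Female	Male	Male	Female	Female	Female	Male	Male	Male
SVL	50.2	44.7	43	50.3	46	46.3	41.1	40.5	42.7
HL	16.8	14.7	13.7	16.5	15.3	15.2	14	13.7	14.3
HW	16.7	14.4	14.2	16.9	15.6	15.8	14.4	14.7	14.6
SL	4.7	4.6	4.5	4.7	4.6	4.8	4.3	4.5	4.5
IND	4.2	3.6	3.6	3.9	3.8	3.9	3.7	3.8	3.6
IOD	4	3.5	3.8	4.1	3.5	3.6	3.7	3.5	3.4
ED	5.3	4.9	4.9	5.3	5	4.9	4.6	4.3	5.1
TD	3.4	3.3	2	2.9	2.6	2.6	1.7	2.2	2.6
TED	2.2	1.5	1.9	2.1	2	2.3	2	1.8	1.7
HNL	10.9	9.6	9.9	10.7	9.9	10.1	9.5	9.2	9.2
FAL	11.9	10.7	9.9	11.3	11.4	10.5	10.2	10.2	10.4
TL	21	18.7	18.2	20.2	20.3	19.5	18	18	17
FTL	19.8	17.8	17.7	18.8	18.4	17.6	16.8	16.9	16.6
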