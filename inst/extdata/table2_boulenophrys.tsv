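species	svl_male_mm	svl_female_mm	eyelid_tubercle_large	vomerine_teeth	tongue_notched	heels	toe_fringes	toe_webbing
B. lushanensis sp. nov.	40.5-44.7	46.0-50.2	F	T	F	F	N	N
B. acuta	27.1-33.0	28.1-33.6	T	F	F	F	N	N
B. angka	31.2-32.1	37.5-39.2	F	F	F	T/N	F	N
B. anlongensis	40.0-45.5	48.9-51.2	F	F	F	T	N	N
B. baishanzuensis	28.4-32.4	/	F	F	F	T	N	F
B. baolongensis	42.0-45.0	/	F	F	T	N	F	F
B. binchuanensis	32.0-36.0	40.2-42.5	F	F	T/F	N	T	N
B. binlingensis	45.1-51.0	/	F	F	T	T	/	N
B. boettgeri	34.5-37.8	39.7-46.8	F	F	T	N	T	N
B. brachykolos	33.7-39.3	33.9-45.9	F	F	F	F	F	N
B. caobangensis	34.9-38.9	/	F	F	F	/	F	N
B. caudoprocta	81.3	/	T	T	F	N	/	N
B. congjiangensis	28.6-33.4	38.4-40.2	F	F	F	T	N	N
B. changyangensis	39.4-43.3	/	F	F	F	T	F	F
B. cheni	26.2-29.5	31.8-34.1	F	F	T	T	T	N
B. chishuiensis	43.4-44.1	44.8-49.8	F	F	F	T	F	N
B. daiyunensis	27.6-28.7	33.7-35.6	F	T	F	T/N	N	N
B. daoji	32.6-33.6	37.5-41.4	F	F	F	F	N	N
B. dalaolingensis	49.9-56.2	50.3-60.0	F	F	T	T	T	T
B. fanjingmontis	58.2-63.6	62.8-72.2	F	T	T	N	T	N
B. dongguanensis	30.2-39.3	/	F	T	F	F	F	N
B. dupanglingensis	37.8-40.2	41.8-45.9	F	F	F	T	F	N
B. elongata	28.2-28.5	35.1-37.6	F	T	F	N	N	F
B. hoanglienensis	37.4-47.6	59.6	F	T	T	/	F	N/F
B. huangnniushienensis	37.9-40.7	/	F	F	F	T/N	F	F
B. fansipanensis	30.9-44.3	41.7-42.5	F	T	T/F	/	F	F
B. fengshunensis	34.3-39.4	42.5-44.9	F	T	F	F	F	N
B. frigida	30.3-31.8	/	F	T	T/F	/	F	F
B. gaolanensis	29.2-30.9	32.0-34.9	F	F	F	F	F	F
B. gutu	34.4-38.0	48.4	F	F	F	F	N	N
B.hengshanensis	35.7-41.2	37.5-50.2	F	F	F	F	F	F
B. jingdongensis	53.0-56.5	63.5	F	T	T	T	T	T
B. hungtai	25.8-33.3	/	F	F	F	F	F	F
B. insularis	36.8-41.2	47.1	F	T	T	F	F	N
B. jiangi	34.4-39.2	39.5-40.4	F	F	F	T	F	N
B. jiulianensis	30.4-33.9	34.1-37.5	F	T	T	T	F	N
B. jinggangensis	35.1-36.7	38.4-41.6	T	T	F	T	N	N
B. liboensis	60.5-67.7	60.8-70.6	T	T	T	T	T	N
B. kuatunensis	26.2-31.4	26.6-37.3	F	F	T	T/F	F/N	F
B. leishanensis	30.4-38.7	42.3	F	F	F	T	F	N
B. lichun	33.5-37.0	47.1	F	T	F	F	F	F
B. lushuiensis	31.0-34.8	/	F	F	T	/	N	N
B. lini	34.1-39.7	37.0-39.9	F	F	F	T	T	N
B. lishuiensis	30.7-34.7	36.9-40.4	F	F	F	/	F	F
B. minor	34.5-41.2	/	F	F	T	T/N	F	N
B. nanlingensis	30.5-37.3	/	F	T	T	T	N	N
B. mirabilis	55.8-61.4	68.5-74.8	T	F	F	T	N	N
B. mufumontana	30.1-30.8	36.3	F	F	F	T	N	N
B. nankunensis	29.9-34.9	39.4-41.9	F	T	F	F	F	N
B. omeimontis	56.0-59.5	68.0-72.5	F	T	T	T	N	N
B. daxuemontis	41.2-46.2	51.8-58.6	F	F	F	T	N	N
B. obesa	35.6	37.5-41.2	F	F	F	F	F	N
B. ombrophila	27.4-34.5	32.8-35.0	F	F	F	F	F	F
B. qianbeiensis	49.3-58.2	/	F	T	T	T	T	T
B. palpebralespinosa	36.2-38.0	/	T	T	F	T	T	T
B. pepe	35.3-36.4	/	F	F	T	F	F	F
B. puningensis	31.7-34.6	37.8-38.3	F	T	F	F	F	N
B. sangzhiensis	54.7	/	F	T	T	T	N	N
B. rubrimera	26.6-30.8	/	F	T	T/F	/	N	F
B. sanmingensis	27.0-29.5	29.5	F	F	T	T	T	N
B. shuichengensis	102.0-118.3	99.8-115.6	T	F	T	/	T	T
B. shimentaina	28.0-30.6	/	F	T	F	T	N	N
B. spinata	47.2-54.4	54.0-55.0	F	F	T	T	T	T
B. shunhuangensis	30.3-33.7	37.6	F	F	F	T	F	F
B. tongboensis	26.5-31.5	/	F	T	T	T	F	F
B. daweimontis	34.0-37.0	40.0-46.0	F	T	/	/	F	F
B. tuberogranulatus	33.2-39.0	50.5	F	F	F	/	F	N
B. wugongensis	31.0-34.1	38.5-42.8	F	F	F	F	F	N
B. wuliangshanensis	27.3-31.6	41.3	F	F	T/F	T	F	F
B. wushanensis	30.4-35.5	38.4	F	F	F	F	F/T	T
B. xiangnanensis	38.6-42.0	44.4	F	F	F	N	T	N
B. xianjuensis	31.0-36.3	41.6	F	F	F	T	N	N
B. xuefengmontis	37.0-38.3	45.3-48.9	F	F	F	T/N	F	F
B. yaoshanensis	32.5-42.6	46.6-47.4	F	F	F	T/N	F	N
B. yangmingensis	33.2-37.1	45.2	F	F	F	T	N	N
B. yezhongensis	41.2-46.2	51.8-58.6	F	T	F	T	N	N
B. yingdeensis	33.2-35.3	36.3-45.8	F	T	F	T/N	F	N
B. yunkaiensis	35.3-40.0	45.3-46.1	F	F	F	T/N	F	N
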