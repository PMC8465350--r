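population	genotype	count
HuB	1	3
HuB	2	1
HuB	4	1
HuB	21	1
HuB	23	4
HuB	28	1
HuB	29	1
HuB	30	3
HuB	36	2
HeN	1	1
HeN	23	4
HeN	24	1
HeN	25	1
HeN	50	1
ZheJ	1	1
ZheJ	7	1
ZheJ	16	1
ZheJ	23	2
NeiM	5	1
NeiM	6	2
NeiM	7	4
ShanX	1	1
ShanX	2	1
ShanX	19	1
ShanX	20	1
ShanX	23	10
ShanX	24	2
ShanX	57	1
JiL	7	14
QingH	1	1
QingH	2	1
QingH	7	2
QingH	23	2
QingH	31	1
QingH	47	1
QingH	51	1
QingH	52	1
XinJ1	23	10
XinJ2	23	13
GuangD	3	1
GuangD	7	1
GuangD	23	3
GuangX	1	7
GuangX	2	1
GuangX	22	1
GuangX	23	4
GuangX	24	6
HaiN	9	1
HaiN	10	1
HaiN	11	10
HaiN	12	1
HaiN	13	1
HaiN	22	1
HaiN	23	2
HaiN	26	1
HaiN	41	4
Dianchi_YunN	23	8
Dianchi_YunN	45	1
Dianchi_YunN	48	1
Dianchi_YunN	49	2
Dianchi_YunN	53	1
GeJ_YunN	1	3
GeJ_YunN	23	6
GeJ_YunN	53	2
GeJ_YunN	58	4
YiM_YunN	8	1
YiM_YunN	33	1
YiM_YunN	34	4
YiM_YunN	35	1
YiM_YunN	37	1
YiM_YunN	38	1
YiM_YunN	39	1
YiM_YunN	53	1
YiM_YunN	54	1
YiM_YunN	55	1
YiM_YunN	56	1
YiM_YunN	58	9
YiM_YunN	59	1
HeiJ_YunN	14	1
HeiJ_YunN	16	1
HeiJ_YunN	18	1
HeiJ_YunN	24	1
HeiJ_YunN	32	1
HeiJ_YunN	34	1
HeiJ_YunN	36	2
HeiJ_YunN	40	1
HeiJ_YunN	42	1
HeiJ_YunN	44	1
HeiJ_YunN	45	1
HeiJ_YunN	46	1
HeiJ_YunN	53	2
GuiZ	15	1
GuiZ	16	5
GuiZ	17	1
GuiZ	27	1
GuiZ	58	1
SiC	23	3
SiC	45	10
Tibet	43	1
Tibet	58	2
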