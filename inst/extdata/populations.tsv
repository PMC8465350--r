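abbrev	name	region	lat	lon	n_isolates
HuB	Hubei	Central	30.6	114.3	17
HeN	Henan	Central	34.7	113.6	8
ZheJ	Zhejiang	East	30.3	120.2	5
NeiM	Nei Mongol	North	40.8	111.7	7
ShanX	Shaanxi	North	34.3	108.9	17
JiL	Jilin	Northeast	43.9	125.3	14
QingH	Qinghai	Northwest	36.6	101.8	10
XinJ1	Kanas Lake, Xinjiang	Northwest	48.7	87	10
XinJ2	Urumqi, Xinjiang	Northwest	43.8	87.6	13
GuangD	Guangdong	South	23.1	113.3	5
GuangX	Guangxi	South	22.8	108.3	19
HaiN	Hainan	South	20	110.3	22
Dianchi_YunN	Dianchi Lake, Yunnan	Southwest	24.8	102.7	13
GeJ_YunN	Gejiu, Yunnan	Southwest	23.4	103.2	15
YiM_YunN	Yimen, Yunnan	Southwest	24.7	102.2	24
HeiJ_YunN	Heijing, Yunnan	Southwest	25.3	101.7	15
GuiZ	Guizhou	Southwest	26.6	106.7	9
SiC	Sichuan	Southwest	30.7	104.1	13
Tibet	Tibet	Southwest	29.7	91.1	3
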