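population	locus	n_alleles	n_private
HuB	A3	1	0
HuB	A5	1	0
HuB	A17	3	0
HuB	A25	2	0
HuB	A51	1	0
HuB	A74	2	0
HuB	A80	1	0
HuB	A83	2	0
HuB	A87	1	0
HuB	A101	2	0
HuB	A103	2	0
HuB	A126	2	0
HuB	A149	2	1
HuB	A154	2	0
HuB	A156	2	0
HuB	A160	3	1
HuB	A177	3	0
HuB	A187	2	0
HuB	A191	3	0
HuB	A192	1	0
HeN	A3	2	0
HeN	A5	1	0
HeN	A17	2	1
HeN	A25	1	0
HeN	A51	1	0
HeN	A74	3	0
HeN	A80	2	0
HeN	A83	2	0
HeN	A87	2	0
HeN	A101	3	0
HeN	A103	3	0
HeN	A126	2	0
HeN	A149	2	0
HeN	A154	2	0
HeN	A156	3	0
HeN	A160	2	0
HeN	A177	2	0
HeN	A187	3	0
HeN	A191	5	0
HeN	A192	2	0
ZheJ	A3	1	0
ZheJ	A5	2	0
ZheJ	A17	3	0
ZheJ	A25	1	0
ZheJ	A51	2	1
ZheJ	A74	3	0
ZheJ	A80	2	0
ZheJ	A83	2	0
ZheJ	A87	1	0
ZheJ	A101	4	0
ZheJ	A103	2	0
ZheJ	A126	2	0
ZheJ	A149	1	0
ZheJ	A154	1	0
ZheJ	A156	3	0
ZheJ	A160	1	0
ZheJ	A177	4	0
ZheJ	A187	2	0
ZheJ	A191	3	0
ZheJ	A192	2	0
NeiM	A3	1	0
NeiM	A5	1	0
NeiM	A17	1	0
NeiM	A25	1	0
NeiM	A51	1	0
NeiM	A74	1	0
NeiM	A80	1	0
NeiM	A83	1	0
NeiM	A87	1	0
NeiM	A101	1	0
NeiM	A103	2	0
NeiM	A126	1	0
NeiM	A149	1	0
NeiM	A154	1	0
NeiM	A156	2	0
NeiM	A160	1	0
NeiM	A177	1	0
NeiM	A187	2	0
NeiM	A191	1	0
NeiM	A192	1	0
ShanX	A3	2	0
ShanX	A5	1	0
ShanX	A17	3	0
ShanX	A25	2	0
ShanX	A51	2	0
ShanX	A74	4	0
ShanX	A80	2	0
ShanX	A83	4	0
ShanX	A87	2	0
ShanX	A101	5	0
ShanX	A103	5	0
ShanX	A126	4	1
ShanX	A149	2	0
ShanX	A154	3	0
ShanX	A156	3	0
ShanX	A160	3	0
ShanX	A177	3	0
ShanX	A187	3	0
ShanX	A191	4	0
ShanX	A192	2	0
JiL	A3	1	0
JiL	A5	1	0
JiL	A17	2	0
JiL	A25	1	0
JiL	A51	1	0
JiL	A74	3	0
JiL	A80	1	0
JiL	A83	2	0
JiL	A87	1	0
JiL	A101	3	0
JiL	A103	2	0
JiL	A126	2	0
JiL	A149	1	0
JiL	A154	3	1
JiL	A156	2	0
JiL	A160	1	0
JiL	A177	1	0
JiL	A187	2	0
JiL	A191	3	1
JiL	A192	1	0
QingH	A3	2	0
QingH	A5	2	0
QingH	A17	3	0
QingH	A25	3	0
QingH	A51	2	0
QingH	A74	4	0
QingH	A80	3	0
QingH	A83	2	0
QingH	A87	2	0
QingH	A101	5	0
QingH	A103	5	0
QingH	A126	3	0
QingH	A149	2	0
QingH	A154	3	0
QingH	A156	3	0
QingH	A160	3	0
QingH	A177	5	0
QingH	A187	3	0
QingH	A191	5	0
QingH	A192	3	0
XinJ1	A3	1	0
XinJ1	A5	1	0
XinJ1	A17	1	0
XinJ1	A25	1	0
XinJ1	A51	1	0
XinJ1	A74	1	0
XinJ1	A80	1	0
XinJ1	A83	1	0
XinJ1	A87	1	0
XinJ1	A101	1	0
XinJ1	A103	2	0
XinJ1	A126	1	0
XinJ1	A149	1	0
XinJ1	A154	1	0
XinJ1	A156	1	0
XinJ1	A160	1	0
XinJ1	A177	1	0
XinJ1	A187	1	0
XinJ1	A191	1	0
XinJ1	A192	1	0
XinJ2	A3	1	0
XinJ2	A5	1	0
XinJ2	A17	2	0
XinJ2	A25	2	0
XinJ2	A51	2	0
XinJ2	A74	1	0
XinJ2	A80	2	0
XinJ2	A83	2	0
XinJ2	A87	1	0
XinJ2	A101	2	0
XinJ2	A103	2	0
XinJ2	A126	2	0
XinJ2	A149	1	0
XinJ2	A154	2	1
XinJ2	A156	2	0
XinJ2	A160	2	0
XinJ2	A177	1	0
XinJ2	A187	2	0
XinJ2	A191	1	0
XinJ2	A192	1	0
GuangD	A3	1	0
GuangD	A5	1	0
GuangD	A17	4	0
GuangD	A25	1	0
GuangD	A51	2	0
GuangD	A74	2	0
GuangD	A80	2	0
GuangD	A83	2	0
GuangD	A87	2	0
GuangD	A101	5	0
GuangD	A103	2	0
GuangD	A126	3	0
GuangD	A149	2	0
GuangD	A154	1	0
GuangD	A156	3	1
GuangD	A160	2	0
GuangD	A177	2	0
GuangD	A187	2	0
GuangD	A191	4	0
GuangD	A192	2	0
GuangX	A3	1	0
GuangX	A5	1	0
GuangX	A17	1	0
GuangX	A25	1	0
GuangX	A51	2	0
GuangX	A74	3	0
GuangX	A80	1	0
GuangX	A83	3	0
GuangX	A87	2	1
GuangX	A101	5	2
GuangX	A103	3	0
GuangX	A126	2	0
GuangX	A149	2	0
GuangX	A154	2	0
GuangX	A156	2	0
GuangX	A160	2	1
GuangX	A177	3	0
GuangX	A187	2	0
GuangX	A191	4	1
GuangX	A192	2	1
HaiN	A3	1	0
HaiN	A5	3	0
HaiN	A17	4	0
HaiN	A25	5	0
HaiN	A51	3	0
HaiN	A74	3	0
HaiN	A80	3	0
HaiN	A83	5	0
HaiN	A87	4	0
HaiN	A101	4	0
HaiN	A103	4	0
HaiN	A126	4	1
HaiN	A149	6	2
HaiN	A154	2	0
HaiN	A156	3	0
HaiN	A160	2	0
HaiN	A177	4	0
HaiN	A187	3	0
HaiN	A191	5	2
HaiN	A192	3	0
Dianchi_YunN	A3	3	0
Dianchi_YunN	A5	3	0
Dianchi_YunN	A17	2	0
Dianchi_YunN	A25	4	0
Dianchi_YunN	A51	2	0
Dianchi_YunN	A74	3	0
Dianchi_YunN	A80	4	0
Dianchi_YunN	A83	4	2
Dianchi_YunN	A87	4	1
Dianchi_YunN	A101	4	0
Dianchi_YunN	A103	5	0
Dianchi_YunN	A126	6	0
Dianchi_YunN	A149	4	0
Dianchi_YunN	A154	2	0
Dianchi_YunN	A156	3	0
Dianchi_YunN	A160	3	0
Dianchi_YunN	A177	4	0
Dianchi_YunN	A187	3	0
Dianchi_YunN	A191	4	1
Dianchi_YunN	A192	4	0
GeJ_YunN	A3	3	0
GeJ_YunN	A5	2	0
GeJ_YunN	A17	3	0
GeJ_YunN	A25	3	0
GeJ_YunN	A51	4	0
GeJ_YunN	A74	3	0
GeJ_YunN	A80	3	0
GeJ_YunN	A83	3	0
GeJ_YunN	A87	3	0
GeJ_YunN	A101	5	0
GeJ_YunN	A103	5	1
GeJ_YunN	A126	2	0
GeJ_YunN	A149	3	0
GeJ_YunN	A154	3	0
GeJ_YunN	A156	4	1
GeJ_YunN	A160	3	1
GeJ_YunN	A177	4	0
GeJ_YunN	A187	3	1
GeJ_YunN	A191	5	0
GeJ_YunN	A192	3	1
YiM_YunN	A3	3	0
YiM_YunN	A5	2	0
YiM_YunN	A17	4	0
YiM_YunN	A25	3	0
YiM_YunN	A51	3	0
YiM_YunN	A74	4	0
YiM_YunN	A80	6	2
YiM_YunN	A83	5	1
YiM_YunN	A87	3	0
YiM_YunN	A101	5	1
YiM_YunN	A103	3	0
YiM_YunN	A126	4	0
YiM_YunN	A149	4	0
YiM_YunN	A154	3	0
YiM_YunN	A156	4	0
YiM_YunN	A160	4	2
YiM_YunN	A177	6	2
YiM_YunN	A187	3	0
YiM_YunN	A191	7	1
YiM_YunN	A192	3	0
HeiJ_YunN	A3	2	0
HeiJ_YunN	A5	5	0
HeiJ_YunN	A17	2	0
HeiJ_YunN	A25	3	0
HeiJ_YunN	A51	3	0
HeiJ_YunN	A74	5	0
HeiJ_YunN	A80	3	0
HeiJ_YunN	A83	5	0
HeiJ_YunN	A87	4	0
HeiJ_YunN	A101	8	1
HeiJ_YunN	A103	4	0
HeiJ_YunN	A126	5	0
HeiJ_YunN	A149	2	0
HeiJ_YunN	A154	4	1
HeiJ_YunN	A156	4	0
HeiJ_YunN	A160	5	0
HeiJ_YunN	A177	5	0
HeiJ_YunN	A187	6	0
HeiJ_YunN	A191	8	1
HeiJ_YunN	A192	5	0
GuiZ	A3	2	0
GuiZ	A5	2	0
GuiZ	A17	3	0
GuiZ	A25	1	0
GuiZ	A51	3	1
GuiZ	A74	2	0
GuiZ	A80	2	0
GuiZ	A83	3	0
GuiZ	A87	2	0
GuiZ	A101	3	1
GuiZ	A103	3	0
GuiZ	A126	3	0
GuiZ	A149	2	0
GuiZ	A154	2	0
GuiZ	A156	3	0
GuiZ	A160	2	0
GuiZ	A177	2	0
GuiZ	A187	3	0
GuiZ	A191	2	0
GuiZ	A192	2	0
SiC	A3	1	0
SiC	A5	2	0
SiC	A17	2	0
SiC	A25	2	0
SiC	A51	2	0
SiC	A74	3	0
SiC	A80	2	0
SiC	A83	3	0
SiC	A87	2	0
SiC	A101	3	0
SiC	A103	3	1
SiC	A126	2	0
SiC	A149	3	0
SiC	A154	1	0
SiC	A156	2	0
SiC	A160	2	0
SiC	A177	3	0
SiC	A187	2	0
SiC	A191	2	0
SiC	A192	2	0
Tibet	A3	2	0
Tibet	A5	2	0
Tibet	A17	2	0
Tibet	A25	2	0
Tibet	A51	3	0
Tibet	A74	2	0
Tibet	A80	2	0
Tibet	A83	2	0
Tibet	A87	3	1
Tibet	A101	1	0
Tibet	A103	2	0
Tibet	A126	2	0
Tibet	A149	2	1
Tibet	A154	2	0
Tibet	A156	2	0
Tibet	A160	3	0
Tibet	A177	1	0
Tibet	A187	3	2
Tibet	A191	1	0
Tibet	A192	2	0
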