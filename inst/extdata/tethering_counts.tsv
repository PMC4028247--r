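# Per-factor (co-)orthologue counts for the 45 tethering factors in the
# curated survey, summed over orthologous groups, for yeast, A. thaliana
# and S. lycopersicum.
factor_id	species	n
Uso1	yeast	1
Uso1	arabidopsis	1
Uso1	tomato	1
COY1	yeast	1
COY1	arabidopsis	1
COY1	tomato	1
Rud3/Grp1	yeast	1
Rud3/Grp1	arabidopsis	0
Rud3/Grp1	tomato	0
Imh1	yeast	1
Imh1	arabidopsis	0
Imh1	tomato	0
VPS11	yeast	1
VPS11	arabidopsis	1
VPS11	tomato	1
VPS16	yeast	1
VPS16	arabidopsis	1
VPS16	tomato	1
VPS18	yeast	1
VPS18	arabidopsis	1
VPS18	tomato	1
VPS33	yeast	1
VPS33	arabidopsis	1
VPS33	tomato	1
VPS39	yeast	1
VPS39	arabidopsis	1
VPS39	tomato	2
VPS41	yeast	1
VPS41	arabidopsis	1
VPS41	tomato	2
VPS8	yeast	1
VPS8	arabidopsis	1
VPS8	tomato	1
VPS3	yeast	1
VPS3	arabidopsis	0
VPS3	tomato	0
SEC3	yeast	1
SEC3	arabidopsis	2
SEC3	tomato	1
SEC5	yeast	1
SEC5	arabidopsis	2
SEC5	tomato	2
SEC6	yeast	1
SEC6	arabidopsis	1
SEC6	tomato	1
SEC8	yeast	1
SEC8	arabidopsis	1
SEC8	tomato	1
SEC10	yeast	1
SEC10	arabidopsis	1
SEC10	tomato	4
SEC15	yeast	1
SEC15	arabidopsis	2
SEC15	tomato	2
EXO70	yeast	1
EXO70	arabidopsis	14
EXO70	tomato	12
EXO84	yeast	1
EXO84	arabidopsis	1
EXO84	tomato	1
Tip20	yeast	1
Tip20	arabidopsis	1
Tip20	tomato	0
DSL1	yeast	1
DSL1	arabidopsis	0
DSL1	tomato	0
SEC39	yeast	1
SEC39	arabidopsis	0
SEC39	tomato	0
COG1	yeast	1
COG1	arabidopsis	1
COG1	tomato	1
COG2	yeast	1
COG2	arabidopsis	1
COG2	tomato	1
COG3	yeast	1
COG3	arabidopsis	1
COG3	tomato	1
COG4	yeast	1
COG4	arabidopsis	1
COG4	tomato	1
COG5	yeast	1
COG5	arabidopsis	1
COG5	tomato	1
COG6	yeast	1
COG6	arabidopsis	1
COG6	tomato	1
COG7	yeast	1
COG7	arabidopsis	1
COG7	tomato	1
COG8	yeast	1
COG8	arabidopsis	1
COG8	tomato	1
VPS52	yeast	1
VPS52	arabidopsis	2
VPS52	tomato	1
VPS53	yeast	1
VPS53	arabidopsis	2
VPS53	tomato	1
VPS54	yeast	1
VPS54	arabidopsis	1
VPS54	tomato	2
VPS51	yeast	1
VPS51	arabidopsis	0
VPS51	tomato	0
Bet3	yeast	1
Bet3	arabidopsis	1
Bet3	tomato	2
Bet5	yeast	1
Bet5	arabidopsis	1
Bet5	tomato	1
Trs20	yeast	1
Trs20	arabidopsis	1
Trs20	tomato	1
Trs23	yeast	1
Trs23	arabidopsis	1
Trs23	tomato	1
Trs31	yeast	1
Trs31	arabidopsis	1
Trs31	tomato	1
Trs33	yeast	1
Trs33	arabidopsis	1
Trs33	tomato	1
Trs85	yeast	1
Trs85	arabidopsis	0
Trs85	tomato	0
Trs120	yeast	1
Trs120	arabidopsis	1
Trs120	tomato	1
Trs130	yeast	1
Trs130	arabidopsis	1
Trs130	tomato	1
Trs65	yeast	1
Trs65	arabidopsis	0
Trs65	tomato	0
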