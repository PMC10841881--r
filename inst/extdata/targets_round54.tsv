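capri_id	casp_id	category	kingdom	uniprot	size	bsa	name	topology	au_ids
T198	T1123	I	V	B6UYJ1	266	1570	Capsid polyprotein VP90	homodimer	AU198
T201	T1132	I	B	A0A072ZNL3	102	1125	Antibiotic biosynthesis monooxygenase	homodimer	AU201
T211	T1153	I	E	Q7L9B9	299	550	Endonuclease/exonuclease/phosphatase family domain-containing protein 1	homodimer	AU211
T225	T1178	I	V	NA	306	3715	NA	homodimer	AU225
T226	T1179	I	V	NA	261	1830	NA	homodimer	AU226
T229	T1187	I	E	Q94EW1	166	935	Nictaba	homodimer	AU229
T192	T1109	II	B	Q8XYF6(D180A)	227	2100	Putative transcription regulator protein	homodimer	AU192
T193	T1110	II	B	Q8XYF6	227	2265	Putative transcription regulator protein	homodimer	AU193
T194	T1113	II	V	A0A4D6BFJ2	193	2750	Uncharacterized protein	homodimer	AU194
T197	T1121	II	B	A0A0H2ZM47	381	1420	DUF3322 and DUF2220 domain-containing protein	homodimer	AU197
T199	T1127	II	E	Q9ZV05	211	3355	L-ornithine N5-acetyltransferase NATA1	homodimer	AU199
T213	T1160	II	designed	NA	48	1080	NA	homodimer	AU213
T214	T1161	II	designed	NA	48	1845	NA	homodimer	AU214
T222	T1173	II	B	Q6MNC5	204	2015	Cell wall surface anchor family protein	homotrimer	AU222
T223	T1174	II	B	Q6ML84	338	5715	Uncharacterized protein	homotrimer	AU223
T224	T1176	II	B	NA	170	5700	Hypothetical protein	homodimer	AU224
T227	T1181	II	V	G0XNW6	688	4940	Tail fiber protein	homotrimer	AU227
T191	H1106	III	B	P0C2N4,P61417	122 114	1440	Yop proteins translocation protein; Chaperone protein	heterodimer	AU191
T200	H1129	III	V	P06971,P23207	747,640	2040	Ferrichrome outer membrane transporter/phage receptor; Receptor-binding protein pb5	heterodimer	AU200
T202	H1134	III	B	A0A0H3CKN4,A0A0M7ENE2	230,313	2000	Ankyrin repeat domain-containing protein; Phospholipase	heterodimer	AU202
T210	H1151	III	B	P9WGI1,P9WF37	112,116	740	RNA polymerase sigma factor SigA; Probably transcriptional regulator WhiB6	heterodimer	AU210
T212	H1157	III	E	G0SCX7,G0SGS2	1029,495	2250	Alpha-1,2-mannosidase; Protein disulphide-isomerase	heterodimer	AU212
T205	H1140	IV	E	P16330,Nanobody	219,132	775	CNPase; Nb	heterodimer	AU205
T206	H1141	IV	E	P16330,Nanobody	219,217	925	CNPase; Nb7e	heterodimer	AU206
T207	H1142	IV	E	P16330,Nanobody	219,128	585	CNPase; Nb8c	heterodimer	AU207
T208	H1143	IV	E	P16330,Nanobody	219,131	770	CNPase; Nb10e	heterodimer	AU208
T209	H1144	IV	E	P16330,Nanobody	219,122	895	CNPase; Nb8d	heterodimer	AU209
T216	H1166	IV	E	P0DTC9,Antibody	130,216 231	1690	Coronavirus nucleocapsid; S24-188 Fab	heterodimer	AU216
T217	H1167	IV	E	P0DTC9,Antibody	130,212 218	1600	Coronavirus nucleocapsid; S24-188 Fab	heterodimer	AU217
T218	H1168	IV	E	P0DTC9,Antibody	130,215 222	1820	Coronavirus nucleocapsid; S24-188 Fab	heterodimer	AU218
T195	T1115	V	E	P27105	288	3350	Stomatin	large	AU195
T203	H1135	V	E	O94901,Q12912	195,25	550-1100	SUN domain-containing protein 1; IRAG2	large	AU203.1;AU203.2
T204	H1137	V	U	NA	266-653	750-6500	NA	large	AU204.1;AU204.2
T219	T1170	V	B	Q5M2B1	318	1900	RuvB	large	AU219
T220	T1171	V	B	Q5M2B1,P66746	318,48	1900,680	RuvB; RuvA	large	AU219;AU220
T221	T1172	V	B	Q5M2B1,P66746	318,48	1900,640	RuvB; RuvA	large	AU219;AU220
T230	T1192	V	E	P43351	418	2225	DNA repair protein RAD52 homolog	large	AU230
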