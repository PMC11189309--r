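gene	n_sites	uniprot	positions
LMNB1	19	P20700	R10;R14;R51;R67;R136;R197;R220;R221;R226;R234;R250;R258;R315;R336;R397;R402;R407;R410;R413
LMNA	17	P02545	R7;R8;R11;R216;R220;R225;R235;R240;R275;R280;R386;R388;R397;R399;R401;R419;R427;R571;R572
HNRNPA2B1	12	P22626	R12;R21;R54;R82;R95;R99;R147;R153;R185;R325;R350;R352
DEK	11	P35659	R29;R58;R65;R75;R93;R107;R116;R153;R168;R208;R215
HNRNPA1	10	P09651	R31;R47;R75;R88;R92;R97;R122;R140;R146;R178
GTF2F1	10	P35269	R46;R49;R73;R101;R180;R181;R206;R413;R422;R424
TOP1	9	P11387	R17;R138;R140;R163;R210;R362;R364;R693;R708
ENO1	9	P06733	R32;R50;R56;R132;R253;R372;R400;R403;R412
HSPA5	9	P11021	R49;R60;R74;R197;R336;R532;R540;R558;R562
PARP1	8	P09874	R10;R156;R208;R282;R340;R355;R496;R806
MBP	7	P02686	R23;R37;R88;R93;R97;R102;R110
CAST	7	P20810	R86;R206;R269;R301;R310;R378;R610
HMGB2	6	P26583	R10;R24;R70;R73;R110;R177
VIM	6	P08670	R113;R145;R304;R310;R424;R450
PTPN22	5	Q9Y2R2	R357;R458;R510;R672;R756
HMGB1	5	P09429	R70;R73;R110;R163;R24
RAF1	5	P04049	R73;R316;R318;R391;R627
PADI4	4	Q9UM07	R218;R372;R374;R394
HSP90AB1	4	P08238	R291;R506;R604;R612
CAT	4	P04040	R5;R263;R458;R522
SSB	4	P05455	R90;R297;R384;R386
TKT	3	P29401	R205;R471;R474
HMGN2	3	P05204	R23;R24;R27
HNRNPD	3	Q14103	R272;R280;R282
CENPB	3	P07199	R66;R588;R593
YBX1	3	P67809	R69;R77;R101
ANXA1	3	P04083	R72;R144;R298
ANXA6	2	P08133	R11;R250
HSPD1	2	P10809	R121;R221
LGALS1	2	P09382	R19;R21
ANXA11	2	P50995	R230;R412
CENPF	2	P49454	R264;R3063
B2M	2	P61769	R32;R101
GPI	2	P06744	R81;R461
TRIM21	2	P19474	R84;R177
ANXA5	1	P08758	R6
SNRPN	1	P63162	R49
CAPNS1	1	P04632	R145
DLAT	1	P10515	R155
CALR	1	P27797	R177
PHB1	1	P35232	R195
RACK1	1	D6R9Z1	R231
PHB2	1	Q99623	R270
NIN	1	Q8N4C6	R1527
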