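# Synthetic gut metabolic module (GMM) definitions (generated fixture)
# module_id<TAB>name<TAB>category<TAB>ko_list
SGMM001	sucrose degradation	carbohydrate degradation	K00058,K00230,K00084,K00213,K00022,K00015,K00045
SGMM002	starch degradation	carbohydrate degradation	K00032,K00083,K00090,K00206,K00225,K00034,K00028,K00053
SGMM003	pectin degradation	carbohydrate degradation	K00189,K00061,K00027,K00236,K00223,K00167
SGMM004	arabinoxylan degradation	carbohydrate degradation	K00106,K00256,K00090,K00086
SGMM005	fructan degradation	carbohydrate degradation	K00008,K00149,K00086,K00024,K00043
SGMM006	lactose degradation	glycoprotein degradation	K00229,K00160,K00048,K00194,K00066
SGMM007	ribose degradation	carbohydrate degradation	K00156,K00125,K00158,K00066,K00041,K00238
SGMM008	rhamnose degradation	carbohydrate degradation	K00044,K00259,K00194,K00018,K00099,K00088,K00102,K00092
SGMM009	mucin degradation	glycoprotein degradation	K00135,K00176,K00136,K00061,K00100,K00243
SGMM010	host glycan degradation	glycoprotein degradation	K00184,K00134,K00003,K00162
SGMM011	glutamate degradation	amino acid degradation	K00026,K00201,K00015,K00257,K00063,K00187,K00115
SGMM012	tryptophan degradation	amino acid degradation	K00222,K00134,K00009,K00157,K00251,K00211
SGMM013	lysine degradation	amino acid degradation	K00032,K00179,K00119,K00022,K00258,K00004
SGMM014	glycolysis	central metabolism	K00042,K00058,K00260,K00119,K00196,K00063
SGMM015	pentose phosphate pathway	central metabolism	K00231,K00247,K00086,K00199,K00022
SGMM016	TCA cycle	central metabolism	K00049,K00201,K00070,K00039,K00108,K00179,K00214
SGMM017	glyoxylate cycle	central metabolism	K00133,K00147,K00255,K00139,K00190
SGMM018	triacylglycerol degradation	lipid degradation	K00060,K00258,K00077,K00017,K00147
SGMM019	glycerol metabolism	lipid degradation	K00123,K00161,K00216,K00109,K00180,K00151,K00222
SGMM020	lactate metabolism	organic acid metabolism	K00116,K00081,K00238,K00247,K00124,K00082,K00191,K00138
SGMM021	succinate metabolism	organic acid metabolism	K00056,K00026,K00084,K00067,K00146,K00222
SGMM022	acetate metabolism	SCFA metabolism	K00148,K00205,K00115,K00250
SGMM023	propionate metabolism	SCFA metabolism	K00088,K00040,K00195,K00156,K00198,K00108
SGMM024	butyrate metabolism	SCFA metabolism	K00252,K00224,K00149,K00235,K00054,K00025,K00036
SGMM025	ethanol metabolism	alcohol metabolism	K00246,K00137,K00144,K00121,K00147,K00028
SGMM026	methanol metabolism	alcohol metabolism	K00186,K00130,K00159,K00138,K00229,K00020,K00046
SGMM027	hydrogen metabolism	gas metabolism	K00230,K00047,K00222,K00157,K00181
SGMM028	nitrogen metabolism	gas metabolism	K00034,K00137,K00025,K00077,K00134
SGMM029	biotin biosynthesis	vitamin metabolism	K00234,K00059,K00223,K00041
SGMM030	folate biosynthesis	vitamin metabolism	K00231,K00084,K00185,K00109
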