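# Synthetic KEGG-style module definitions (generated fixture, not real KEGG data)
# module_id<TAB>definition
SM00001	K00234+K00004 (K00181,K00210)
SM00002	K00216 K00091
SM00003	K00166 K00050,K00008,K00230
SM00004	K00224 K00235,K00066
SM00005	K00177+K00094 K00125 K00102 K00081 K00057+K00081-K00174
SM00006	K00260 K00053+K00021 K00147+K00046 K00016,K00078,K00094 (K00087,K00045)
SM00007	K00064+K00117 K00055+K00212-K00087 (K00119,K00202) K00185,K00115,K00132
SM00008	K00080 K00116 K00012+K00068
SM00009	K00228 K00081 K00219,K00051 K00223,K00240,K00206 --
SM00010	K00213,K00183 K00010,K00037 K00055+K00182-K00096 K00246+K00033
SM00011	K00118+K00070 K00052,K00202 K00086+K00006
SM00012	(K00027,K00088) K00257,K00259
SM00013	K00124 K00043+K00247-K00062 -- K00064+K00069
SM00014	K00062 K00108,K00206 K00111+K00113-K00189 K00134
SM00015	K00221+K00134-K00253 (K00256,K00207) K00089+K00119
SM00016	K00029+K00209 K00189
SM00017	K00049+K00166 (K00127,K00037) K00071+K00016 K00006,K00157
SM00018	K00059+K00226 K00064+K00211-K00007 K00163
SM00019	K00198+K00018 K00070,K00163,K00231 K00229,K00119 K00251 K00239+K00115
SM00020	K00016+K00052 (K00232,K00180) K00163
SM00021	K00177+K00147 K00044 K00089+K00036
SM00022	K00145 K00123+K00183 K00129 K00143+K00167-K00089 K00169
SM00023	K00041,K00045,K00234 K00008+K00028 (K00097,K00033)
SM00024	(K00062,K00150) K00113 K00093 K00113+K00077-K00204
SM00025	K00030,K00188,K00240 K00081,K00023,K00140 K00243+K00181
SM00026	(K00254,K00066) K00193,K00124 K00007+K00188
SM00027	K00251,K00205 (K00210,K00089) K00230,K00056 K00179
SM00028	K00067+K00047 (K00214,K00142) K00142+K00210-K00041
SM00029	K00194 K00008 K00097 (K00027,K00101) (K00131,K00041)
SM00030	(K00257,K00229) K00255
SM00031	K00209,K00242,K00130 (K00155,K00207) K00243,K00035
SM00032	(K00194,K00024) (K00076,K00042) K00123 K00226+K00146 K00019+K00098
SM00033	K00143,K00084 K00251,K00193 K00195
SM00034	-- K00145,K00165 K00250
SM00035	K00196 K00073+K00210-K00132 K00223 K00067,K00214,K00043
SM00036	K00226 K00243 K00150 K00226+K00206-K00141 K00053
SM00037	(K00237,K00091) K00048+K00135-K00102 K00018 K00232+K00067
SM00038	K00002,K00138,K00187 K00114 K00059 (K00057,K00160) K00104+K00042-K00125
SM00039	K00074 K00202,K00028 K00132,K00059,K00159
SM00040	(K00105,K00021) -- K00242+K00215
SM00041	K00190+K00145 K00169,K00245 K00244
SM00042	K00155+K00207 K00094+K00064 K00153+K00143 (K00166,K00021)
SM00043	(K00078,K00005) K00008,K00213 K00201,K00049,K00197
SM00044	(K00158,K00126) K00126+K00220 K00197,K00125 K00044+K00117
SM00045	K00129 K00211 K00236+K00224
SM00046	K00136 K00083+K00184 K00086 K00043,K00052
SM00047	K00078,K00106,K00181 K00078,K00008 K00156+K00006
SM00048	K00050+K00228 (K00186,K00138) -- K00174,K00219 K00023,K00024,K00117
SM00049	K00224+K00150 K00222,K00221
SM00050	K00035 K00193
SM00051	K00175+K00138 K00232+K00163
SM00052	(K00240,K00149) K00117+K00196-K00090 K00055+K00073-K00042
SM00053	-- K00189,K00068,K00202 (K00117,K00066) K00166
SM00054	-- K00237 K00172+K00105-K00053 K00105+K00187
SM00055	K00092+K00076 K00056,K00045,K00231 K00240
SM00056	K00141 K00072,K00087
SM00057	K00124 K00159+K00251
SM00058	K00131,K00016 K00074,K00120,K00171 K00095,K00054
SM00059	(K00212,K00236) K00008
SM00060	K00194,K00175,K00128 (K00255,K00251) K00023+K00080
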