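case_id,histotype,variant,pattern_m1
case_001,HGSOC,p.R175H,OE
case_002,HGSOC,p.R175H,OE
case_003,HGSOC,p.R175H,OE
case_004,HGSOC,p.R175H,OE
case_005,HGSOC,p.R175H,OE
case_006,HGSOC,p.R175H,OE
case_007,HGSOC,p.R175H,OE
case_008,HGSOC,p.R175H,OE
case_009,HGSOC,p.R175H,OE
case_010,HGSOC,p.Y220C,OE
case_011,HGSOC,p.Y220C,OE
case_012,HGSOC,p.Y220C,OE
case_013,HGSOC,p.Y220C,OE
case_014,HGSOC,p.Y220C,OE
case_015,HGSOC,p.Y220C,OE
case_016,HGSOC,p.R273H,OE
case_017,HGSOC,p.R273H,OE
case_018,HGSOC,p.R273H,OE
case_019,HGSOC,p.R273H,OE
case_020,HGSOC,p.R273H,OE
case_021,HGSOC,p.R248Q,OE
case_022,HGSOC,p.R282W,OE
case_023,HGSOC,p.G245S,OE
case_024,HGSOC,p.Y163C,OE
case_025,HGSOC,p.H179R,OE
case_026,HGSOC,p.C176F,OE
case_027,HGSOC,p.V157F,OE
case_028,HGSOC,p.R158L,OE
case_029,HGSOC,p.L194R,OE
case_030,HGSOC,p.I195T,OE
case_031,HGSOC,p.Y234C,OE
case_032,HGSOC,p.S241F,OE
case_033,HGSOC,p.C242F,OE
case_034,HGSOC,p.G266E,OE
case_035,HGSOC,p.R280T,OE
case_036,HGSOC,p.E285K,OE
case_037,HGSOC,p.R248Q,OE
case_038,HGSOC,p.R282W,OE
case_039,HGSOC,p.G245S,OE
case_040,HGSOC,p.Y163C,OE
case_041,HGSOC,p.H179R,OE
case_042,HGSOC,p.C176F,OE
case_043,HGSOC,p.V157F,OE
case_044,HGSOC,p.R158L,OE
case_045,HGSOC,p.L194R,OE
case_046,HGSOC,p.I195T,OE
case_047,HGSOC,p.Y234C,OE
case_048,HGSOC,p.S241F,OE
case_049,HGSOC,p.C242F,OE
case_050,HGSOC,p.G266E,OE
case_051,HGSOC,p.R280T,OE
case_052,HGSOC,p.E285K,OE
case_053,HGSOC,p.R248Q,OE
case_054,HGSOC,p.R282W,OE
case_055,HGSOC,p.G245S,OE
case_056,HGSOC,p.Y163C,OE
case_057,HGSOC,p.H179R,OE
case_058,HGSOC,p.C176F,OE
case_059,HGSOC,p.V157F,OE
case_060,HGSOC,p.R158L,OE
case_061,HGSOC,p.L194R,OE
case_062,HGSOC,p.I195T,OE
case_063,HGSOC,p.Y234C,OE
case_064,HGSOC,p.S241F,OE
case_065,HGSOC,p.C242F,OE
case_066,HGSOC,p.G266E,OE
case_067,HGSOC,p.R280T,OE
case_068,HGSOC,p.E285K,OE
case_069,HGSOC,p.R248Q,OE
case_070,HGSOC,p.R282W,OE
case_071,HGSOC,p.G245S,OE
case_072,HGSOC,p.Y163C,OE
case_073,HGSOC,p.H179R,OE
case_074,HGSOC,p.C176F,OE
case_075,HGSOC,p.V157F,OE
case_076,HGSOC,p.R158L,OE
case_077,HGSOC,p.L194R,OE
case_078,HGSOC,p.I195T,OE
case_079,HGSOC,p.Y234C,OE
case_080,HGSOC,p.S241F,OE
case_081,HGSOC,p.C242F,OE
case_082,HGSOC,p.G266E,OE
case_083,HGSOC,p.R280T,OE
case_084,HGSOC,p.E285K,OE
case_085,HGSOC,p.R248Q,OE
case_086,HGSOC,p.R282W,OE
case_087,HGSOC,p.G245S,OE
case_088,HGSOC,p.Y163C,OE
case_089,HGSOC,p.H179R,OE
case_090,HGSOC,p.C176F,OE
case_091,HGSOC,p.V157F,OE
case_092,HGSOC,p.R158L,OE
case_093,HGSOC,p.L194R,OE
case_094,HGSOC,p.I195T,OE
case_095,HGSOC,p.Y234C,OE
case_096,HGSOC,p.S241F,OE
case_097,HGSOC,p.C242F,OE
case_098,HGSOC,p.G266E,OE
case_099,HGSOC,p.R280T,OE
case_100,HGSOC,p.E285K,OE
case_101,HGSOC,p.R248Q,OE
case_102,HGSOC,p.R282W,OE
case_103,HGSOC,p.G245S,OE
case_104,HGSOC,p.Y163C,OE
case_105,HGSOC,p.H179R,OE
case_106,HGSOC,p.C176F,OE
case_107,HGSOC,p.V157F,OE
case_108,HGSOC,p.R158L,OE
case_109,HGSOC,p.L194R,OE
case_110,HGSOC,p.I195T,OE
case_111,EC,p.Y234C,OE
case_112,EC,p.S241F,OE
case_113,EC,p.C242F,OE
case_114,EC,p.G266E,OE
case_115,EC,p.R280T,OE
case_116,HGSOC,p.I255del,OE
case_117,HGSOC,p.I255del,OE
case_118,HGSOC,p.R342X,OE
case_119,HGSOC,p.E349X,OE
case_120,HGSOC,c.672+1G>A,OE
case_121,HGSOC,c.673-1G>A,OE
case_122,HGSOC,p.P58fs,CA
case_123,HGSOC,p.S90fs,CA
case_124,HGSOC,p.Q144fs,CA
case_125,HGSOC,p.P151fs,CA
case_126,HGSOC,p.S166fs,CA
case_127,HGSOC,p.P27fs,CA
case_128,HGSOC,p.A39fs,CA
case_129,HGSOC,p.T102fs,CA
case_130,HGSOC,p.V122fs,CA
case_131,HGSOC,p.C141fs,CA
case_132,HGSOC,p.P177fs,CA
case_133,HGSOC,p.H193fs,CA
case_134,HGSOC,p.E204fs,CA
case_135,HGSOC,p.V97fs,CA
case_136,EC,p.L130fs,CA
case_137,EC,p.K139fs,CA
case_138,HGSOC,p.R196X,CA
case_139,HGSOC,p.R196X,CA
case_140,HGSOC,p.R196X,CA
case_141,HGSOC,p.R196X,CA
case_142,HGSOC,p.W91X,CA
case_143,HGSOC,p.Q104X,CA
case_144,HGSOC,p.E171X,CA
case_145,HGSOC,p.R65X,CA
case_146,HGSOC,p.S90X,CA
case_147,HGSOC,p.E62X,CA
case_148,HGSOC,p.Q136X,CA
case_149,HGSOC,p.E198X,CA
case_150,HGSOC,p.W146X,CA
case_151,HGSOC,c.356-2delA,CA
case_152,HGSOC,c.96+1G>A,CA
case_153,HGSOC,c.97-1G>A,CA
case_154,HGSOC,c.375+1G>A,CA
case_155,HGSOC,c.376-1G>A,CA
case_156,HGSOC,c.559+1G>A,CA
case_157,HGSOC,c.560-1G>A,CA
case_158,HGSOC,c.782+1G>A,CA
case_159,HGSOC,c.783-1G>A,CA
case_160,HGSOC,c.919+1G>A,CA
case_161,HGSOC,c.920-1G>A,CA
case_162,HGSOC,c.993+1G>A,CA
case_163,HGSOC,p.F270fs*25,CY
case_164,HGSOC,p.L265fs*30,CY
case_165,HGSOC,p.R306X,CY
case_166,HGSOC,p.R306X,CY
case_167,HGSOC,p.T256fs*90,WT
case_168,HGSOC,p.D259fs*86,WT
case_169,HGSOC,p.S261fs*23,WT
case_170,HGSOC,p.G262fs*60,WT
case_171,HGSOC,c.994-1G>A,WT
case_172,HGSOC,c.1100+1G>A,WT
case_173,HGSOC,c.1101-1G>A,WT
case_174,HGSOC,NDM,WT
case_175,HGSOC,NDM,WT
case_176,HGSOC,NDM,WT
case_177,EC,p.P72P,WT
case_178,EC,NDM,WT
case_179,EC,NDM,WT
case_180,EC,NDM,WT
case_181,EC,NDM,WT
case_182,EC,NDM,WT
case_183,EC,NDM,WT
case_184,EC,NDM,WT
case_185,EC,NDM,WT
case_186,EC,NDM,WT
case_187,EC,NDM,WT
case_188,EC,NDM,WT
case_189,EC,NDM,WT
case_190,EC,NDM,WT
case_191,EC,NDM,WT
case_192,EC,NDM,WT
case_193,EC,NDM,WT
case_194,EC,NDM,WT
case_195,EC,NDM,WT
case_196,EC,NDM,WT
case_197,EC,NDM,WT
case_198,EC,NDM,WT
case_199,EC,NDM,WT
case_200,EC,NDM,WT
case_201,EC,NDM,WT
case_202,EC,NDM,WT
case_203,EC,NDM,WT
case_204,EC,NDM,WT
case_205,EC,NDM,WT
case_206,EC,NDM,WT
case_207,EC,NDM,WT
case_208,EC,NDM,WT
case_209,EC,NDM,WT
case_210,EC,NDM,WT
case_211,EC,NDM,WT
case_212,EC,NDM,WT
case_213,EC,NDM,WT
case_214,EC,NDM,WT
case_215,EC,NDM,WT
case_216,EC,NDM,WT
case_217,EC,NDM,WT
case_218,EC,NDM,WT
case_219,EC,NDM,WT
case_220,EC,NDM,WT
case_221,EC,NDM,WT
case_222,EC,NDM,WT
case_223,EC,NDM,WT
case_224,EC,NDM,WT
case_225,EC,NDM,WT
case_226,EC,NDM,WT
case_227,EC,NDM,WT
case_228,EC,NDM,WT
case_229,EC,NDM,WT
case_230,EC,NDM,WT
case_231,EC,NDM,WT
case_232,EC,NDM,WT
case_233,EC,NDM,WT
case_234,EC,NDM,WT
case_235,EC,NDM,WT
case_236,EC,NDM,WT
case_237,EC,NDM,WT
case_238,EC,NDM,WT
case_239,EC,NDM,WT
case_240,EC,NDM,WT
case_241,EC,NDM,WT
case_242,EC,NDM,WT
case_243,EC,NDM,WT
case_244,EC,NDM,WT
case_245,EC,NDM,WT
case_246,EC,NDM,WT
case_247,EC,NDM,WT
case_248,EC,NDM,WT
case_249,EC,NDM,WT
case_250,HGSOC,p.R248W,unscored
case_251,HGSOC,p.C176Y,unscored
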