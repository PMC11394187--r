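case_id,pred,truth
case_001,positive,positive
case_002,positive,positive
case_003,positive,positive
case_004,positive,positive
case_005,positive,positive
case_006,positive,positive
case_007,positive,positive
case_008,positive,positive
case_009,positive,positive
case_010,positive,positive
case_011,positive,positive
case_012,positive,positive
case_013,positive,positive
case_014,positive,positive
case_015,positive,positive
case_016,positive,positive
case_017,positive,positive
case_018,positive,positive
case_019,positive,positive
case_020,positive,positive
case_021,positive,positive
case_022,positive,positive
case_023,positive,positive
case_024,positive,positive
case_025,positive,positive
case_026,positive,positive
case_027,positive,positive
case_028,positive,positive
case_029,positive,positive
case_030,positive,positive
case_031,positive,positive
case_032,positive,positive
case_033,positive,positive
case_034,positive,positive
case_035,positive,positive
case_036,positive,positive
case_037,positive,positive
case_038,positive,positive
case_039,positive,positive
case_040,positive,positive
case_041,positive,positive
case_042,positive,positive
case_043,positive,positive
case_044,positive,positive
case_045,positive,positive
case_046,positive,positive
case_047,positive,positive
case_048,positive,positive
case_049,positive,positive
case_050,positive,positive
case_051,positive,positive
case_052,positive,positive
case_053,positive,positive
case_054,positive,positive
case_055,positive,negative
case_056,positive,negative
case_057,positive,negative
case_058,positive,negative
case_059,positive,negative
case_060,positive,negative
case_061,positive,negative
case_062,positive,negative
case_063,positive,negative
case_064,positive,negative
case_065,positive,negative
case_066,positive,negative
case_067,positive,negative
case_068,positive,negative
case_069,positive,negative
case_070,negative,positive
case_071,negative,positive
case_072,negative,positive
case_073,negative,positive
case_074,negative,positive
case_075,negative,positive
case_076,negative,positive
case_077,negative,positive
case_078,negative,positive
case_079,negative,positive
case_080,negative,positive
case_081,negative,positive
case_082,negative,positive
case_083,negative,negative
case_084,negative,negative
case_085,negative,negative
case_086,negative,negative
case_087,negative,negative
case_088,negative,negative
case_089,negative,negative
case_090,negative,negative
case_091,negative,negative
case_092,negative,negative
case_093,negative,negative
case_094,negative,negative
case_095,negative,negative
case_096,negative,negative
case_097,negative,negative
case_098,negative,negative
case_099,negative,negative
case_100,negative,negative
case_101,negative,negative
case_102,negative,negative
case_103,negative,negative
case_104,negative,negative
case_105,negative,negative
case_106,negative,negative
case_107,negative,negative
case_108,negative,negative
case_109,negative,negative
case_110,negative,negative
case_111,negative,negative
case_112,negative,negative
case_113,negative,negative
case_114,negative,negative
case_115,negative,negative
case_116,negative,negative
case_117,negative,negative
case_118,negative,negative
case_119,negative,negative
case_120,negative,negative
case_121,negative,negative
case_122,negative,negative
case_123,negative,negative
case_124,negative,negative
case_125,negative,negative
case_126,negative,negative
case_127,negative,negative
case_128,negative,negative
case_129,negative,negative
case_130,negative,negative
case_131,negative,negative
case_132,negative,negative
case_133,negative,negative
case_134,negative,negative
case_135,negative,negative
case_136,negative,negative
case_137,negative,negative
case_138,negative,negative
case_139,negative,negative
case_140,negative,negative
case_141,negative,negative
case_142,negative,negative
case_143,negative,negative
case_144,negative,negative
case_145,negative,negative
case_146,negative,negative
case_147,negative,negative
case_148,negative,negative
case_149,negative,negative
case_150,negative,negative
case_151,negative,negative
case_152,negative,negative
case_153,negative,negative
case_154,negative,negative
case_155,negative,negative
case_156,negative,negative
case_157,negative,negative
case_158,negative,negative
case_159,negative,negative
case_160,negative,negative
case_161,negative,negative
case_162,negative,negative
case_163,negative,negative
case_164,negative,negative
case_165,negative,negative
case_166,negative,negative
case_167,negative,negative
case_168,negative,negative
case_169,negative,negative
case_170,negative,negative
case_171,negative,negative
case_172,negative,negative
case_173,negative,negative
case_174,negative,negative
case_175,negative,negative
case_176,negative,negative
case_177,negative,negative
case_178,negative,negative
case_179,negative,negative
case_180,negative,negative
case_181,negative,negative
case_182,negative,negative
case_183,negative,negative
case_184,negative,negative
case_185,negative,negative
case_186,negative,negative
case_187,negative,negative
case_188,negative,negative
case_189,negative,negative
case_190,negative,negative
case_191,negative,negative
case_192,negative,negative
case_193,negative,negative
case_194,negative,negative
case_195,negative,negative
case_196,negative,negative
case_197,negative,negative
case_198,negative,negative
case_199,negative,negative
case_200,negative,negative
case_201,negative,negative
case_202,negative,negative
case_203,negative,negative
case_204,negative,negative
case_205,negative,negative
case_206,negative,negative
case_207,negative,negative
case_208,negative,negative
case_209,negative,negative
case_210,negative,negative
case_211,negative,negative
case_212,negative,negative
case_213,negative,negative
case_214,negative,negative
case_215,negative,negative
case_216,negative,negative
case_217,negative,negative
case_218,negative,negative
case_219,negative,negative
case_220,negative,negative
case_221,negative,negative
case_222,negative,negative
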