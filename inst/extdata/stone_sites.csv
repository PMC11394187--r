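case_id,pred,truth
site_001,stone,stone
site_002,stone,stone
site_003,stone,stone
site_004,stone,stone
site_005,stone,stone
site_006,stone,stone
site_007,stone,stone
site_008,stone,stone
site_009,stone,stone
site_010,stone,stone
site_011,stone,stone
site_012,stone,stone
site_013,stone,stone
site_014,stone,stone
site_015,stone,stone
site_016,stone,stone
site_017,stone,stone
site_018,stone,stone
site_019,stone,stone
site_020,stone,stone
site_021,stone,stone
site_022,stone,stone
site_023,stone,stone
site_024,stone,stone
site_025,stone,stone
site_026,stone,stone
site_027,stone,stone
site_028,stone,stone
site_029,stone,stone
site_030,stone,stone
site_031,stone,stone
site_032,stone,stone
site_033,stone,stone
site_034,stone,stone
site_035,stone,stone
site_036,stone,stone
site_037,stone,stone
site_038,stone,stone
site_039,stone,stone
site_040,stone,stone
site_041,stone,stone
site_042,stone,stone
site_043,stone,stone
site_044,stone,stone
site_045,stone,stone
site_046,stone,stone
site_047,stone,stone
site_048,stone,stone
site_049,stone,stone
site_050,stone,stone
site_051,stone,stone
site_052,stone,stone
site_053,stone,stone
site_054,stone,stone
site_055,stone,stone
site_056,stone,stone
site_057,stone,stone
site_058,stone,stone
site_059,stone,stone
site_060,stone,stone
site_061,stone,stone
site_062,stone,stone
site_063,stone,stone
site_064,stone,stone
site_065,stone,stone
site_066,stone,stone
site_067,stone,stone
site_068,stone,stone
site_069,stone,stone
site_070,stone,stone
site_071,stone,stone
site_072,stone,stone
site_073,stone,stone
site_074,stone,stone
site_075,stone,stone
site_076,stone,stone
site_077,stone,stone
site_078,stone,stone
site_079,stone,residual_stone
site_080,stone,residual_stone
site_081,stone,residual_stone
site_082,stone,residual_stone
site_083,stone,residual_stone
site_084,stone,residual_stone
site_085,stone,residual_stone
site_086,stone,residual_stone
site_087,stone,residual_stone
site_088,stone,residual_stone
site_089,stone,residual_stone
site_090,stone,residual_stone
site_091,stone,residual_stone
site_092,stone,residual_stone
site_093,stone,residual_stone
site_094,stone,residual_stone
site_095,stone,residual_stone
site_096,stone,residual_stone
site_097,stone,residual_stone
site_098,stone,residual_stone
site_099,stone,residual_stone
site_100,stone,residual_stone
site_101,stone,residual_stone
site_102,stone,residual_stone
site_103,stone,residual_stone
site_104,stone,residual_stone
site_105,stone,residual_stone
site_106,stone,residual_stone
site_107,stone,residual_stone
site_108,residual_stone,stone
site_109,residual_stone,stone
site_110,residual_stone,stone
site_111,residual_stone,stone
site_112,residual_stone,stone
site_113,residual_stone,stone
site_114,residual_stone,stone
site_115,residual_stone,stone
site_116,residual_stone,stone
site_117,residual_stone,residual_stone
site_118,residual_stone,residual_stone
site_119,residual_stone,residual_stone
site_120,residual_stone,residual_stone
site_121,residual_stone,residual_stone
site_122,residual_stone,residual_stone
site_123,residual_stone,residual_stone
site_124,residual_stone,residual_stone
site_125,residual_stone,residual_stone
site_126,residual_stone,residual_stone
site_127,residual_stone,residual_stone
site_128,residual_stone,residual_stone
site_129,residual_stone,residual_stone
site_130,residual_stone,residual_stone
site_131,residual_stone,residual_stone
site_132,residual_stone,residual_stone
site_133,residual_stone,residual_stone
site_134,residual_stone,residual_stone
site_135,residual_stone,residual_stone
site_136,residual_stone,residual_stone
site_137,residual_stone,residual_stone
site_138,residual_stone,residual_stone
site_139,residual_stone,residual_stone
site_140,residual_stone,residual_stone
site_141,residual_stone,residual_stone
site_142,residual_stone,residual_stone
site_143,residual_stone,residual_stone
site_144,residual_stone,residual_stone
site_145,residual_stone,residual_stone
site_146,residual_stone,residual_stone
site_147,residual_stone,residual_stone
site_148,residual_stone,residual_stone
site_149,residual_stone,residual_stone
site_150,residual_stone,residual_stone
site_151,residual_stone,residual_stone
site_152,residual_stone,residual_stone
site_153,residual_stone,residual_stone
site_154,residual_stone,residual_stone
site_155,residual_stone,residual_stone
site_156,residual_stone,residual_stone
site_157,residual_stone,residual_stone
site_158,residual_stone,residual_stone
site_159,residual_stone,residual_stone
site_160,residual_stone,residual_stone
site_161,residual_stone,residual_stone
site_162,residual_stone,residual_stone
site_163,residual_stone,residual_stone
site_164,residual_stone,residual_stone
site_165,residual_stone,residual_stone
site_166,residual_stone,residual_stone
site_167,residual_stone,residual_stone
site_168,residual_stone,residual_stone
site_169,residual_stone,residual_stone
site_170,residual_stone,residual_stone
site_171,residual_stone,residual_stone
site_172,residual_stone,residual_stone
site_173,residual_stone,residual_stone
site_174,residual_stone,residual_stone
site_175,residual_stone,residual_stone
site_176,residual_stone,residual_stone
site_177,residual_stone,residual_stone
site_178,residual_stone,residual_stone
site_179,residual_stone,residual_stone
site_180,residual_stone,residual_stone
site_181,residual_stone,residual_stone
site_182,residual_stone,residual_stone
site_183,residual_stone,residual_stone
site_184,residual_stone,residual_stone
site_185,residual_stone,residual_stone
site_186,residual_stone,residual_stone
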