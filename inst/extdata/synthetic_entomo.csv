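week,total_captures,positive_traps,observed_traps
2009-W23,301,395,416
2009-W24,269,391,411
2009-W25,180,393,415
2009-W26,217,374,413
2009-W27,195,397,418
2009-W28,133,381,412
2009-W29,227,369,415
2009-W30,123,384,410
2009-W31,105,383,417
2009-W32,185,364,408
2009-W33,154,377,414
2009-W34,142,355,404
2009-W35,195,368,410
2009-W36,201,388,411
2009-W37,224,375,408
2009-W38,185,377,409
2009-W39,150,385,413
2009-W40,208,363,409
2009-W41,201,380,417
2009-W42,177,380,411
2009-W43,238,379,409
2009-W44,229,390,416
2009-W45,182,382,412
2009-W46,167,379,414
2009-W47,183,378,412
2009-W48,196,378,408
2009-W49,260,376,404
2009-W50,176,396,414
2009-W51,212,377,408
2009-W52,149,385,409
2009-W53,198,373,412
2010-W01,142,381,406
2010-W02,83,373,411
2010-W03,103,375,414
2010-W04,242,372,416
2010-W05,256,397,416
2010-W06,212,389,408
2010-W07,228,386,408
2010-W08,235,383,407
2010-W09,253,382,408
2010-W10,149,407,417
2010-W11,197,370,406
2010-W12,174,382,411
2010-W13,233,377,414
2010-W14,276,398,412
2010-W15,233,396,409
2010-W16,216,393,410
2010-W17,205,391,413
2010-W18,212,366,405
2010-W19,171,397,412
2010-W20,234,381,408
2010-W21,278,395,414
2010-W22,299,399,413
2010-W23,208,400,414
2010-W24,217,386,410
2010-W25,210,384,406
2010-W26,191,382,410
2010-W27,192,377,408
2010-W28,166,382,415
2010-W29,274,382,411
2010-W30,304,387,410
2010-W31,175,401,414
2010-W32,203,375,410
2010-W33,149,383,417
2010-W34,135,366,412
2010-W35,172,376,412
2010-W36,249,376,413
2010-W37,235,395,413
2010-W38,230,380,410
2010-W39,265,394,415
2010-W40,235,382,414
2010-W41,163,379,412
2010-W42,97,371,413
2010-W43,145,364,413
2010-W44,255,369,411
2010-W45,256,380,411
2010-W46,225,395,413
2010-W47,252,386,412
2010-W48,182,389,410
2010-W49,283,370,412
2010-W50,148,392,410
2010-W51,131,383,419
2010-W52,177,367,402
2011-W01,244,379,416
2011-W02,216,393,410
2011-W03,199,381,411
2011-W04,136,384,410
2011-W05,205,366,414
2011-W06,207,380,416
2011-W07,251,381,413
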