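individual,sample,locality,host,mll,CIR-Ms-G08,CIR-Ms-G403,CIR-Ms-B03,CIR-Ms-C08,CIR-Ms-G01,CIR-Ms-E01,CIR-Ms-G12,CIR-Ms-E03,CIR-Ms-D02,CIR-Ms-G02
Ms5,Ms5,NA,NA,A,229/229,253/253,215/215,189/203,206/210,245/247,214/216,176/176,220/228,250/316
Ms30,Ms30,NA,NA,A,229/229,253/253,215/215,189/203,204/206,245/247,214/216,176/176,220/228,250/318
Ms31,Ms31,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,228/230,254/314
Ms41,Ms41,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/226,252/314
Ms42,Ms42,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/226,254/314
Ms301,Ms301,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,248/312
Ms302,Ms302,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,248/314
Ms303,Ms303,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/298
Ms304,Ms304,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/310
Ms305,Ms305,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/312
Ms306,Ms306,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/314
Ms307,Ms307,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/316
Ms308,Ms308,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214//216,176/176,220/228,250/318
Ms309,Ms309,NA,NA,A,229/229,253//253,215/215,189//203,206/206,245/247,214/216,176/176,220/228,250/343
Ms310,Ms310,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,250/345
Ms311,Ms311,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,252/312
Ms312,Ms312,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,252/314
Ms313,Ms313,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,254/312
Ms314,Ms314,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,254/314
Ms315,Ms315,NA,NA,A,229/229,253/253,215/215,189/203,206/206,245/247,214/216,176/176,220/228,256/314
Ms1,Ms1,NA,NA,B,233/233,253/259,213/215,197/199,185/206,247/247,212/216,188/193,226/232,199/199
Ms2,Ms2,NA,NA,B,233/233,253/259,213/215,197/199,185/206,247/247,212/216,188/193,226/252,199/199
Ms121,Ms121,NA,NA,B,233/233,253/259,213/215,197/199,185/206,247/247,212/216,188/191,226/232,199/199
Ms122,Ms122,NA,NA,B,233/233,253/259,213/215,197/199,185/206,247/247,212/216,188/191,226/232,199/201
Ms6,Ms6,NA,NA,C,233/233,251/259,213/213,197/199,185/210,247/247,212/216,186/193,228/234,199/199
Ms7,Ms7,NA,NA,C,233/233,251/259,213/213,197/199,185/210,247/247,204/212,186/193,228/232,199/199
Ms8,Ms8,NA,NA,C,233/233,251/259,213/213,197/199,185/212,247/247,212/216,186/193,228/232,199/199
Ms11,Ms11,NA,NA,C,233/233,251/259,213/213,197/199,185/210,247/247,212/216,186/193,228/232,199/199
Ms12,Ms12,NA,NA,C,233/233,251/259,213/213,195/197,185/210,247/247,212/216,186/193,228/232,199/205
Ms15,Ms15,NA,NA,C,233/233,251/259,213/213,197/199,185/210,247/247,212/216,186/193,228/232,199/201
Ms16,Ms16,NA,NA,C,233/233,251/259,213/213,195/197,185/210,247/247,212/216,186/193,228/232,199/203
Ms21,Ms21,NA,NA,C,233/233,251/259,213/213,195/197,185/210,247/247,212/216,186/193,228/234,199/203
Ms9,Ms9,NA,NA,D,233/233,251/259,213/213,197/199,185/206,247/247,212/216,186/188,226/234,201/201
Ms10,Ms10,NA,NA,D,233/233,251/259,213/213,197/199,185/206,247/247,212/218,186/188,226/234,201/201
Ms32,Ms32,NA,NA,E,229/229,253/253,215/215,197/197,198/206,245/245,208/212,216/224,220/222,216/216
Ms33,Ms33,NA,NA,E,229/229,253/253,215/215,197/197,198/206,245/245,208/212,224/224,220/222,216/216
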