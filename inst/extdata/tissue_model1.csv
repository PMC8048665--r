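label,name,chi_mean,a_tissue,b_tissue,is_brain_tissue,is_piecewise_constant
1,Caudate,0.044,-0.012,1.118,1,0
2,GlobusPallidus,0.131,-0.026,0.843,1,0
3,Putamen,0.038,-0.025,1.852,1,0
4,RedNucleus,0.100,-0.044,1.780,1,0
5,DentateNucleus,0.152,-0.064,1.708,1,0
6,SubstantiaNigra,0.111,-0.075,1.491,1,0
7,Thalamus,0.020,-0.086,1.275,1,0
8,WhiteMatter,-0.030,-0.078,1.147,1,0
9,GrayMatter,0.020,-0.095,1.402,1,0
10,CSF,0.019,-0.006,0.067,0,0
11,Blood,0.190,-0.058,0.047,0,0
12,Fat,0.019,0.000,0.000,0,1
13,Bone,-2.100,0.000,0.000,0,1
14,Air,9.200,0.000,0.000,0,1
15,Muscle,0.000,0.000,0.000,0,1
16,Calcification,-3.300,-0.012,0.000,0,0
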