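id,name,smiles,formula_printed,ic50_pde10a_uM,ki_a1_nM,ki_a2a_nM,logp_printed,tpsa_printed
1,2-amino-6-(4-fluorophenyl)-4-phenylpyridine-3-carbonitrile,Nc1nc(-c2ccc(F)cc2)cc(-c2ccccc2)c1C#N,C18H12FN3,NA,NA,NA,NA,NA
2,2-amino-6-(4-hydroxyphenyl)-4-phenylpyridine-3-carbonitrile,Nc1nc(-c2ccc(O)cc2)cc(-c2ccccc2)c1C#N,C18H13N3O,NA,NA,NA,NA,NA
3,"2-amino-4-phenyl-6-(1,3-thiazol-2-yl)pyridine-3-carbonitrile",Nc1nc(-c2nccs2)cc(-c2ccccc2)c1C#N,C15H10N4S,2.0,NA,NA,3.1,103.9
4,2-amino-6-(1-methyl-1H-pyrrol-2-yl)-4-phenylpyridine-3-carbonitrile,Nc1nc(-c2cccn2C)cc(-c2ccccc2)c1C#N,C17H14N4,NA,NA,NA,NA,NA
5,2-amino-4-(2-methoxyphenyl)-6-phenylpyridine-3-carbonitrile,Nc1nc(-c2ccccc2)cc(-c2ccccc2OC)c1C#N,C19H15N3O,NA,NA,NA,NA,NA
6,"2-amino-4-(2,4-dimethoxyphenyl)-6-phenylpyridine-3-carbonitrile",Nc1nc(-c2ccccc2)cc(-c2ccc(OC)cc2OC)c1C#N,C20H17N3O2,5.7,NA,NA,4.0,81.2
7,"2-amino-4-(2H-1,3-benzodioxol-5-yl)-6-phenylpyridine-3-carbonitrile",Nc1nc(-c2ccccc2)cc(-c2ccc3OCOc3c2)c1C#N,C19H13N3O2,NA,NA,NA,NA,NA
8,2-amino-4-cyclohexyl-6-phenylpyridine-3-carbonitrile,Nc1nc(-c2ccccc2)cc(C2CCCCC2)c1C#N,C18H19N3,2.4,294,NA,NA,NA
9,2-amino-4-cyclohexyl-6-(2-fluorophenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2F)cc(C2CCCCC2)c1C#N,C18H18FN3,NA,NA,NA,NA,NA
10,2-amino-4-cyclohexyl-6-(2-methylphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2C)cc(C2CCCCC2)c1C#N,C19H21N3,NA,NA,NA,NA,NA
11,2-amino-4-cyclohexyl-6-(thiophen-2-yl)pyridine-3-carbonitrile,Nc1nc(-c2cccs2)cc(C2CCCCC2)c1C#N,C16H17N3S,NA,NA,NA,NA,NA
12,2-amino-4-cyclohexyl-6-(thiophen-3-yl)pyridine-3-carbonitrile,Nc1nc(-c2ccsc2)cc(C2CCCCC2)c1C#N,C16H17N3S,0.9,NA,NA,4.7,90.9
13,2-amino-4-cyclohexyl-6-(furan-2-yl)pyridine-3-carbonitrile,Nc1nc(-c2ccco2)cc(C2CCCCC2)c1C#N,C16H17N3O,NA,NA,NA,NA,NA
14,2-amino-6-(2-fluorophenyl)-4-(4-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2F)cc(-c2ccc(OC)cc2)c1C#N,C19H14FN3O,NA,NA,NA,NA,NA
15,2-amino-4-(4-methoxyphenyl)-6-(2-methylphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2C)cc(-c2ccc(OC)cc2)c1C#N,C20H17N3O,1.5,NA,NA,4.4,71.9
16,2-amino-6-(furan-2-yl)-4-(4-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccco2)cc(-c2ccc(OC)cc2)c1C#N,C17H13N3O2,3.2,34,41,3.1,85.1
17,2-amino-6-(4-hydroxyphenyl)-4-(4-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccc(O)cc2)cc(-c2ccc(OC)cc2)c1C#N,C19H15N3O2,NA,NA,NA,NA,NA
18,"2-amino-4,6-bis(2-fluorophenyl)pyridine-3-carbonitrile",Nc1nc(-c2ccccc2F)cc(-c2ccccc2F)c1C#N,C18H11F2N3,NA,78,948,NA,NA
19,2-amino-6-(2-fluorophenyl)-4-(2-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2F)cc(-c2ccccc2OC)c1C#N,C19H14FN3O,NA,NA,NA,NA,NA
20,2-amino-4-(2-methoxyphenyl)-6-(2-methylphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccccc2C)cc(-c2ccccc2OC)c1C#N,C20H17N3O,NA,NA,NA,NA,NA
21,2-amino-6-(furan-2-yl)-4-(2-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccco2)cc(-c2ccccc2OC)c1C#N,C17H13N3O2,10.0,NA,95,NA,NA
22,2-amino-6-(4-hydroxyphenyl)-4-(2-methoxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccc(O)cc2)cc(-c2ccccc2OC)c1C#N,C19H15N3O2,5.6,NA,NA,3.7,92.2
23,2-amino-4-(2-chlorophenyl)-6-(4-hydroxyphenyl)pyridine-3-carbonitrile,Nc1nc(-c2ccc(O)cc2)cc(-c2ccccc2Cl)c1C#N,C18H12ClN3O,NA,NA,NA,NA,NA
24,"2-amino-4,6-bis(4-hydroxyphenyl)pyridine-3-carbonitrile",Nc1nc(-c2ccc(O)cc2)cc(-c2ccc(O)cc2)c1C#N,C18H13N3O2,3.1,NA,NA,3.4,103.2
25,2-amino-4-(furan-2-yl)-6-(thiophen-3-yl)pyridine-3-carbonitrile,Nc1nc(-c2ccsc2)cc(-c2ccco2)c1C#N,C14H9N3OS,5.1,NA,55,NA,NA
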