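candidate_id,name,smiles
D001,ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O
D002,caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
D003,paracetamol,CC(=O)Nc1ccc(O)cc1
D004,aspirin,CC(=O)Oc1ccccc1C(=O)O
D005,naproxen,COc1ccc2cc(ccc2c1)C(C)C(=O)O
D006,carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21
D007,diclofenac,OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl
D008,atrazine,CCNc1nc(Cl)nc(NC(C)C)n1
D009,nicotine,CN1CCCC1c1cccnc1
D010,benzocaine,CCOC(=O)c1ccc(N)cc1
D011,lidocaine,CCN(CC)CC(=O)Nc1c(C)cccc1C
D012,procaine,CCN(CC)CCOC(=O)c1ccc(N)cc1
D013,salbutamol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
D014,atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
D015,propranolol,CC(C)NCC(O)COc1cccc2ccccc12
D016,warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
D017,ketoprofen,CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1
D018,gemfibrozil,Cc1ccc(C)c(OCCCC(C)(C)C(=O)O)c1
D019,bezafibrate,CC(C)(Oc1ccc(CCNC(=O)c2ccc(Cl)cc2)cc1)C(=O)O
D020,clofibric acid,CC(C)(Oc1ccc(Cl)cc1)C(=O)O
D021,trimethoprim,COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC
D022,sulfadiazine,Nc1ccc(cc1)S(=O)(=O)Nc1ncccn1
D023,sulfapyridine,Nc1ccc(cc1)S(=O)(=O)Nc1ccccn1
D024,theophylline,Cn1c(=O)c2[nH]cnc2n(C)c1=O
D025,cotinine,CN1C(=O)CCC1c1cccnc1
D026,tramadol,COc1cccc(c1)C1(O)CCCCC1CN(C)C
D027,venlafaxine,COc1ccc(cc1)C(CN(C)C)C1(O)CCCCC1
D028,fluoxetine,CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1
D029,citalopram,CN(C)CCCC1(OCc2cc(ccc21)C#N)c1ccc(F)cc1
D030,diazepam,CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1
D031,oxazepam,OC1N=C(c2ccccc2)c2cc(Cl)ccc2NC1=O
D032,temazepam,CN1c2ccc(Cl)cc2C(=NC(O)C1=O)c1ccccc1
D033,codeine,COc1ccc2CC3C4C=CC(O)C5Oc1c2C45CCN3C
D034,morphine,Oc1ccc2CC3C4C=CC(O)C5Oc1c2C45CCN3C
D035,amitriptyline,CN(C)CCC=C1c2ccccc2CCc2ccccc21
D036,nortriptyline,CNCCC=C1c2ccccc2CCc2ccccc21
D037,ranitidine,CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1
D038,cimetidine,CC1=C(CSCCNC(=NC)NC#N)N=CN1
D039,metformin,CN(C)C(=N)NC(=N)N
D040,furosemide,NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl
D041,hydrochlorothiazide,NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O
D042,chlorpromazine,CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21
D043,promethazine,CC(CN1c2ccccc2Sc2ccccc21)N(C)C
D044,terbutaline,CC(C)(C)NCC(O)c1cc(O)cc(O)c1
D045,clenbuterol,CC(C)(C)NCC(O)c1cc(Cl)c(N)c(Cl)c1
D046,isoproterenol,CC(C)NCC(O)c1ccc(O)c(O)c1
D047,dopamine,NCCc1ccc(O)c(O)c1
D048,serotonin,NCCc1c[nH]c2ccc(O)cc12
D049,melatonin,COc1ccc2[nH]cc(CCNC(C)=O)c2c1
D050,tryptophan,NC(Cc1c[nH]c2ccccc12)C(=O)O
D051,tyrosine,NC(Cc1ccc(O)cc1)C(=O)O
D052,phenylalanine,NC(Cc1ccccc1)C(=O)O
D053,ephedrine,CNC(C)C(O)c1ccccc1
D054,amphetamine,CC(N)Cc1ccccc1
D055,methamphetamine,CNC(C)Cc1ccccc1
D056,mdma,CC(Cc1ccc2OCOc2c1)NC
D057,ketamine,CNC1(CCCCC1=O)c1ccccc1Cl
D058,phencyclidine,C1CCC(CC1)(c1ccccc1)N1CCCCC1
D059,cocaine,COC(=O)C1C(OC(=O)c2ccccc2)CC2CCC1N2C
D060,benzoylecgonine,OC(=O)C1C(OC(=O)c2ccccc2)CC2CCC1N2C
D061,gabapentin,NCC1(CC(=O)O)CCCCC1
D062,pregabalin,CC(C)CC(CN)CC(=O)O
D063,valproic acid,CCCC(CCC)C(=O)O
D064,levetiracetam,CCC(N1CCCC1=O)C(N)=O
D065,lamotrigine,Nc1nnc(c(N)n1)-c1cccc(Cl)c1Cl
D066,primidone,CCC1(c2ccccc2)C(=O)NCNC1=O
D067,phenytoin,O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1
D068,phenobarbital,CCC1(c2ccccc2)C(=O)NC(=O)NC1=O
D069,caffeic acid,OC(=O)C=Cc1ccc(O)c(O)c1
D070,ferulic acid,COc1cc(C=CC(=O)O)ccc1O
D071,vanillin,COc1cc(C=O)ccc1O
D072,coumarin,O=c1ccc2ccccc2o1
D073,umbelliferone,Oc1ccc2ccc(=O)oc2c1
D074,quercetin,Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O
D075,resveratrol,Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1
D076,bisphenol a,CC(C)(c1ccc(O)cc1)c1ccc(O)cc1
D077,triclosan,Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl
D078,methylparaben,COC(=O)c1ccc(O)cc1
D079,propylparaben,CCCOC(=O)c1ccc(O)cc1
D080,benzophenone,O=C(c1ccccc1)c1ccccc1
D081,oxybenzone,COc1ccc(C(=O)c2ccccc2)c(O)c1
D082,octocrylene,CCC(CC)COC(=O)C(=C(c1ccccc1)c1ccccc1)C#N
D083,deet,CCN(CC)C(=O)c1cccc(C)c1
D084,imidacloprid,[O-][N+](=O)NC1=NCCN1Cc1ccc(Cl)nc1
D085,thiacloprid,N#CNC1=NCCSN1Cc1ccc(Cl)nc1
D086,acetamiprid,CC(=NC#N)N(C)Cc1ccc(Cl)nc1
D087,carbaryl,CNC(=O)Oc1cccc2ccccc12
D088,carbofuran,CNC(=O)Oc1cccc2c1OC(C)(C)C2
D089,aldicarb,CNC(=O)ON=CC(C)(C)SC
D090,simazine,CCNc1nc(Cl)nc(NCC)n1
D091,terbuthylazine,CCNc1nc(Cl)nc(NC(C)(C)C)n1
D092,metolachlor,CCc1cccc(C)c1N(C(C)COC)C(=O)CCl
D093,alachlor,CCc1cccc(CC)c1N(COC)C(=O)CCl
D094,acetochlor,CCOCN(c1c(C)cccc1CC)C(=O)CCl
D095,diuron,CN(C)C(=O)Nc1ccc(Cl)c(Cl)c1
D096,isoproturon,CC(C)c1ccc(NC(=O)N(C)C)cc1
D097,chlorotoluron,Cc1ccc(NC(=O)N(C)C)cc1Cl
D098,mecoprop,Cc1ccc(OC(C)C(=O)O)c(Cl)c1
D099,2-4-d,OC(=O)COc1ccc(Cl)cc1Cl
D100,mcpa,Cc1cc(Cl)ccc1OCC(=O)O
D101,bentazone,CC(C)N1S(=O)(=O)c2ccccc2NC1=O
D102,glyphosate,OC(=O)CNCP(=O)(O)O
D103,chlorpyrifos,CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl
D104,malathion,CCOC(=O)CC(SP(=S)(OC)OC)C(=O)OCC
D105,dimethoate,CNC(=O)CSP(=S)(OC)OC
D106,parathion,CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]
D107,benzotriazole,c1ccc2[nH]nnc2c1
D108,tolyltriazole,Cc1ccc2[nH]nnc2c1
D109,saccharin,O=C1NS(=O)(=O)c2ccccc21
D110,acesulfame,CC1=CC(=O)NS(=O)(=O)O1
D111,sucralose,OCC1OC(OC2(CCl)OC(CO)C(O)C2O)C(O)C(O)C1Cl
D112,aspartame,COC(=O)C(Cc1ccccc1)NC(=O)C(N)CC(=O)O
D113,cyclamate,OS(=O)(=O)NC1CCCCC1
D114,erythromycin fragment,CCC(O)C(C)CC(C)C(=O)OC
D115,azithromycin fragment,CNC1CCCC(C)OC1C
D116,clarithromycin fragment,COC1C(C)CC(C)OC1O
D117,tetracycline fragment,CN(C)C1C(O)C(C(N)=O)C(=O)C1O
D118,ciprofloxacin,OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O
D119,norfloxacin,CCn1cc(C(=O)O)c(=O)c2cc(N3CCNCC3)c(F)cc21
D120,ofloxacin,CC1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(cn1c23)C(=O)O
D121,nalidixic acid,CCn1cc(C(=O)O)c(=O)c2ccc(C)nc21
D122,clindamycin fragment,CCCC1CC(N(C)C1)C(=O)NC(C(C)Cl)C1OC(SC)C(O)C(O)C1O
D123,lincomycin fragment,CCCC1CC(N(C)C1)C(=O)NC(C(C)O)C1OC(SC)C(O)C(O)C1O
D124,amoxicillin,CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O
D125,penicillin g,CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O
D126,cephalexin,CC1=C(N2C(SC1)C(NC(=O)C(N)c1ccccc1)C2=O)C(=O)O
D127,naphthalene,c1ccc2ccccc2c1
D128,anthracene,c1ccc2cc3ccccc3cc2c1
D129,phenanthrene,c1ccc2c(c1)ccc1ccccc12
D130,pyrene,c1cc2ccc3cccc4ccc(c1)c2c34
D131,fluoranthene,c1ccc2c(c1)-c1cccc3cccc2c13
D132,biphenyl,c1ccc(cc1)-c1ccccc1
D133,dibenzofuran,c1ccc2c(c1)oc1ccccc12
D134,carbazole,c1ccc2c(c1)[nH]c1ccccc12
D135,quinoline,c1ccc2ncccc2c1
D136,isoquinoline,c1cc2ccncc2cc1
D137,indole,c1ccc2[nH]ccc2c1
D138,benzimidazole,c1ccc2[nH]cnc2c1
D139,adenine,Nc1ncnc2[nH]cnc12
D140,guanine,Nc1nc2[nH]cnc2c(=O)[nH]1
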