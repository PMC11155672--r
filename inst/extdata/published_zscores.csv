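cas,chemical,group,10,30,50,100
90-43-7,2-phenylphenol,high,-0.17755904,-0.835403038,0.527326135,1.050863864
139-07-1,benzyldimethyldodecylammonium chloride,high,2.78478466,7.52545311,0.830889353,2.25191063
80-05-7,bisphenol A,high,-0.258125177,-0.346607755,0.127835223,1.002009593
332-41-5,diazinon,high,NT,0.857304437,NT,1.416176111
300-76-5,"dimethyl-1,2-dibromo-2,2-dichlorethyl phosphate",high,0.532899005,-0.484680664,-0.018537122,1.829875555
115-32-2,dicofol,high,NT,1.030403236,NT,0.316375902
25115-18-4,methylbenzethonium chloride,high,6.65914045,6.7145512,7.72694365,5.4143412
7173-51-5,didecyldimethylammonium chloride,high,1.59554513,1.396318643,0.731390858,0.94670189
375-95-1,norflurazon,high,NT,0.274425578,NT,6.347934415
148-98-8,perfluoro nonanoic acid,high,-0.294215382,0.126864892,-0.0514802,1.668737891
68694-11-1,thiabendazole,high,0.30853793,2.290591694,-0.112301184,3.548542028
78-33-1,tri-p-tert-butylphenyl phosphate,high,NT,1.137348756,NT,-0.523046153
68694-11-1,triflumizole,high,1.524173433,0.959842876,0.312115328,1.19880601
111-76-2,ethylene glycol butyl ether (EGBE),low,-0.493188189,-0.760018538,-0.428279589,-0.786605971
3194-55-6,hexabromocyclodecane (HBCD),low,-0.532066923,-0.637397676,-0.262285387,-0.635415477
121-75-5,malathion,low,-0.57865188,-0.633130582,-0.195971923,-0.080772843
75-09-2,methylene chloride,low,-0.760359221,-0.205061778,-0.145673888,-0.320872732
2528-16-7,monobenzyl phthalate,low,-0.384659645,-0.081544854,-0.425217575,-0.614814203
335-76-2,perfluorodecanoic acid,low,-0.760359221,-0.402192131,NDA,-1.219646999
52645-53-1,permethrin,low,-0.55800923,-0.735099931,-0.198504842,-0.561941711
175013-18-0,pyraclostrobin,low,-0.436371926,-0.067060827,-0.242144092,-0.523376499
302-79-4,retinoic acid (RA),low,-0.654868704,-0.096655283,-0.429698571,-0.586138019
13674-87-8,"tris(1,3-dichloro-2-propyl) phosphate (TDCIPP)",low,-0.56212385,-0.236069063,-0.422525695,-0.350506139
112281-77-3,tetraconazole,low,-0.369829188,-0.574755817,-0.344775632,-1.124919234
1119-97-7,tetradonium bromide,low,-0.760359221,-0.166809423,-0.486457849,-0.864417879
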