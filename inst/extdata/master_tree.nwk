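((((((((((((((ailMel1:0.03854019703,((lepWed1:0.02002160645,odoRosDi:0.02064385875):0.01734764946,musFur1:0.04613997497):0.002879093616):0.009005888384,canFam3:0.05339127565):0.01185166857,felCat5:0.05020331605):0.03285617057,((((((bosTau7:0.02168740723,((capHir1:0.01157093136,oviAri3:0.01246322594):0.0049716126,panHod1:0.01522587482):0.01465511149):0.0662523666,(orcOrc1:0.006371664911,turTru2:0.01086552617):0.06014682602):0.01216198069,susScr3:0.0796745271):0.006785823323,(camFer1:0.01240650215,vicPac2:0.01096629635):0.06374554586):0.02551888691,(cerSim1:0.04977357056,equCab2:0.061454379):0.02510111297):0.00331214686,((eptFus1:0.03248546656,(myoDav1:0.02344332842,myoLuc2:0.01567729315):0.02193849809):0.09455328094,(pteAle1:0.005833353548,pteVam1:0.01611220178):0.07567400302):0.02385546003):0.002057771224):0.004845253848,(conCri1:0.1239823369,(eriEur2:0.1696142244,sorAra2:0.1934205791):0.02079474546):0.0235875333):0.01477733374,((((((chrAsi1:0.1017903453,echTel2:0.1749615473):0.01592632003,eleEdw1:0.1516860647):0.006610995228,oryAfe1:0.08326528894):0.008243787904,(loxAfr3:0.06812658238,triMan1:0.06198982615):0.0224994529):0.03384011363,dasNov3:0.1342602666):0.005989703247,(((macEug2:0.1270943532,sarHar1:0.09944141622):0.02717055443,monDom5:0.1181200712):0.1802966572,ornAna1:0.4322118716):0.2206952867):0.01316436193):0.01425600689,((((((cavPor3:0.09048639907,(chiLan1:0.05332953299,octDeg1:0.08476954109):0.01287861561):0.02118937782,hetGla2:0.08588673524):0.07432515556,speTri2:0.08896424642):0.006291577528,((((criGri1:0.04084640027,mesAur1:0.04456203524):0.02314125062,micOch1:0.06932402649):0.01947113467,(mm10:0.05273642272,rn5:0.05576007402):0.04435347588):0.08380065137,jacJac1:0.1438649666):0.04270536633):0.01663675397,(ochPri3:0.1256544445,oryCun2:0.07131655591):0.06535533418):0.009050428462,tupChi1:0.1191189141):0.003894252213):0.01379370868,otoGar3:0.108738222):0.04299750653,(calJac3:0.02474184521,saiBol1:0.02096868307):0.02784675729):0.0135408115,(chlSab1:0.007693724903,((macFas5:0.001292320552,rheMac3:0.00713015786):0.002951690224,papHam1:0.005199240711):0.002049749893):0.01566263562):0.007043113559,nomLeu3:0.01770384793):0.002187630666,ponAbe2:0.0164503644):0.005572327638,gorGor3:0.007765177171):0.001382639829,hg19:0.005957477577,panTro4:0.006721826689);
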