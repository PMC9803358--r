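species	common_name	hairless	marine	adult_weight_g
ailMel1	giant_panda	0	0	100000
bosTau7	cow	0	0	750000
calJac3	marmoset	0	0	350
camFer1	bactrian_camel	0	0	450000
canFam3	dog	0	0	30000
capHir1	goat	0	0	60000
cavPor3	guinea_pig	0	0	900
cerSim1	white_rhinoceros	1	0	2100000
chiLan1	chinchilla	0	0	500
chlSab1	green_monkey	0	0	5000
chrAsi1	cape_golden_mole	0	0	40
conCri1	star_nosed_mole	0	0	50
criGri1	chinese_hamster	0	0	35
dasNov3	armadillo	1	0	4500
echTel2	lesser_hedgehog_tenrec	0	0	180
eleEdw1	cape_elephant_shrew	0	0	50
eptFus1	big_brown_bat	0	0	18
equCab2	horse	0	0	450000
eriEur2	hedgehog	0	0	800
felCat5	cat	0	0	4000
gorGor3	gorilla	0	0	150000
hetGla2	naked_mole_rat	1	0	35
hg19	human	1	0	70000
jacJac1	lesser_egyptian_jerboa	0	0	55
lepWed1	weddell_seal	0	1	400000
loxAfr3	african_elephant	1	0	4800000
macEug2	tammar_wallaby	0	0	7000
macFas5	crab_eating_macaque	0	0	5000
mesAur1	golden_hamster	0	0	120
micOch1	prairie_vole	0	0	45
mm10	mouse	0	0	20
monDom5	gray_short_tailed_opossum	0	0	100
musFur1	ferret	0	0	1200
myoDav1	davids_myotis	0	0	6
myoLuc2	little_brown_bat	0	0	8
nomLeu3	gibbon	0	0	6000
ochPri3	american_pika	0	0	150
octDeg1	degu	0	0	200
odoRosDi	pacific_walrus	1	1	1200000
orcOrc1	killer_whale	1	1	4000000
ornAna1	platypus	0	0	1500
oryAfe1	aardvark	0	0	60000
oryCun2	rabbit	0	0	1800
otoGar3	bushbaby	0	0	1100
oviAri3	sheep	0	0	80000
panHod1	tibetan_antelope	0	0	35000
panTro4	chimpanzee	0	0	50000
papHam1	hamadryas_baboon	0	0	20000
ponAbe2	orangutan	0	0	60000
pteAle1	black_flying_fox	0	0	700
pteVam1	large_flying_fox	0	0	1000
rheMac3	rhesus_macaque	0	0	8000
rn5	rat	0	0	300
saiBol1	squirrel_monkey	0	0	800
sarHar1	tasmanian_devil	0	0	8000
sorAra2	common_shrew	0	0	10
speTri2	ground_squirrel	0	0	150
susScr3	pig	1	0	150000
triMan1	manatee	1	1	450000
tupChi1	chinese_tree_shrew	0	0	150
turTru2	bottlenose_dolphin	1	1	250000
vicPac2	alpaca	0	0	60000
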