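species	subspecies	collection_id	genbank_entry	fragments	profile_group	no_insilico_data	note
B. adolescentis		ATCC 15703	AF210319	31-36-81-103-339		FALSE	
B. angulatum		ATCC 27535	AF240568	42-54-59-139-296		FALSE	
B. animalis	animalis	ATCC 25527	AY004273	17-53-86-97-114-223		FALSE	
B. animalis	lactis	DSM 10140	AY004282	71-86-96-114-223		FALSE	accession shared with B. pseudolongum subsp. pseudolongum as printed
B. asteroides		ATCC 25910	AF240570	30-38-75-97-109-242		FALSE	
B. bifidum		ATCC 29521	AY004280	22-31-59-181-297		FALSE	
B. boum		ATCC 27917	AY004285	22-117-200-251		FALSE	
B. breve		ATCC 15700	AF240566	106-139-139-200		FALSE	
B. catenulatum		ATCC 27539	AY004272	53-198-338		FALSE	collection id also printed for B. minimum; suspected typo kept as printed
B. choerinum		ATCC 27686	AY013247	36-42-51-52-54-59-97-200		FALSE	
B. coryneforme		ATCC 25911	AY004275	16-32-54-158-338		FALSE	
B. cuniculi		ATCC 27916	AY004283	16-42-53-70-128-281		FALSE	
B. dentium		ATCC 27534	AF240572	22-31-42-68-130-139-158		FALSE	
B. gallicum		ATCC 49850	AF240575	42-253-297		FALSE	
B. gallinarum		ATCC 33777	AY004279	16-31-42-81-139-281		FALSE	
B. indicum		ATCC 25912	AF240574	16-32-36-42-45-123-296		FALSE	
B. longum	longum	ATCC 15707	AF240578	42-113-138-139-158	longum	FALSE	
B. longum	infantis	ATCC 15697	AF240577	42-113-138-139-158	longum	FALSE	
B. longum	suis	ATCC 27533	AY013248	42-113-138-139-158	longum	FALSE	
B. merycicum		ATCC 49391	AY004277	22-31-42-59-139-297		FALSE	
B. minimum		ATCC 27539	AY004284	16-51-60-66-70-327		FALSE	collection id also printed for B. catenulatum; suspected typo kept as printed
B. pseudocatenulatum		ATCC 27919	AY004274	42-53-198-297		FALSE	
B. pseudolongum	pseudolongum	ATCC 25526	AY004282	17-22-30-32-42-42-109-297		FALSE	accession shared with B. animalis subsp. lactis as printed
B. pseudolongum	globosum	ATCC 25865	AF286736	16-17-22-30-32-42-109-323		FALSE	
B. pullorum		ATCC 27685	AY004278	16-31-36-42-81-87-297		FALSE	
B. ruminantium		ATCC 49390	AF240571	31-106-114-339		FALSE	
B. subtile		ATCC 27537				TRUE	no in-silico profile available; plus-sign flag in the source table is unexplained
B. thermacidophilum	porcinum	LMG 21689	AY004276	20-42-53-59-97-139-180	thermacidophilum	FALSE	accession shared between both thermacidophilum subspecies as printed
B. thermacidophilum	thermacidophilum	LMG 21395	AY004276	20-42-53-59-97-139-180	thermacidophilum	FALSE	accession shared between both thermacidophilum subspecies as printed
B. thermophilum		ATCC 25525	AF240567	54-59-117-139-222		FALSE	
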