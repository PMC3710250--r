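species	subspecies	strain	source	reassigned_species	reassigned_subspecies
B. animalis	animalis	T169	Rat		
B. animalis	animalis	T6/1	Rat		
B. animalis	lactis	P23	Chicken		
B. animalis	lactis	F439	Sewage		
B. animalis	lactis	Ra20	Rabbit		
B. animalis	lactis	Ra18	Rabbit		
B. animalis	lactis	P32	Chicken		
B. bifidum		B1764	Infant		
B. bifidum		B2091	Infant		
B. bifidum		B7613	Preterm infant		
B. bifidum		B2009	Infant		
B. bifidum		B2531	Infant		
B. breve		B2274	Infant		
B. breve		B2150	Infant		
B. breve		B8279	Preterm infant		
B. breve		B8179	Preterm infant		
B. breve		Re1	Infant		
B. catenulatum		B1955	Infant	B. adolescentis	
B. catenulatum		B684	Adult		
B. catenulatum		B2120	Infant		
B. pseudocatenulatum		B1286	Infant		
B. pseudocatenulatum		B7003			
B. pseudocatenulatum		B8452			
B. dentium		Chz7	Chimpanzee		
B. dentium		Chz15	Chimpanzee		
B. longum	longum	PCB133	Adult		
B. longum	infantis	B7740	Preterm infant		
B. longum	infantis	B7710	Preterm infant		
B. longum	suis	Su864	Piglet	B. breve	
B. longum	suis	Su932	Piglet		
B. longum	suis	Su905	Piglet		
B. longum	suis	Su908	Piglet		
B. pseudolongum	pseudolongum	MB9	Chicken		
B. pseudolongum	pseudolongum	MB10	Mouse		
B. pseudolongum	pseudolongum	MB8	Chicken		
B. pseudolongum	globosum	Ra27	Rabbit		
B. pseudolongum	globosum	VT366	Calf		
B. pseudolongum	globosum	T19	Rat		
B. pseudolongum	globosum	P113	Chicken		
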