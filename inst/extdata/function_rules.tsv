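rank	pattern	category
genus	g__Bradyrhizobium	nitrogen_fixation
genus	g__Azospirillum	nitrogen_fixation
genus	g__Rhizobium	nitrogen_fixation
genus	g__Mesorhizobium	nitrogen_fixation
genus	g__Frankia	nitrogen_fixation
genus	g__Azotobacter	nitrogen_fixation
genus	g__Nitrospira	aerobic_nitrite_oxidation
genus	g__Nitrospira	nitrification
genus	g__Nitrobacter	aerobic_nitrite_oxidation
genus	g__Nitrobacter	nitrification
genus	g__Nitrosomonas	aerobic_ammonia_oxidation
genus	g__Nitrosomonas	nitrification
genus	g__Pseudomonas	nitrate_reduction
genus	g__Pseudomonas	chemoheterotrophy
genus	g__Geobacter	nitrate_reduction
genus	g__Arthrobacter	chemoheterotrophy
genus	g__Streptomyces	chemoheterotrophy
genus	g__Bacillus	chemoheterotrophy
genus	g__Sphingomonas	chemoheterotrophy
genus	g__Rubrobacter	chemoheterotrophy
genus	g__Clostridium	fermentation
genus	g__Clostridium	chemoheterotrophy
genus	g__Lactobacillus	fermentation
genus	g__Methylobacter	methanotrophy
genus	g__Methylobacterium	methanol_oxidation
genus	g__Thiobacillus	dark_sulfur_oxidation
genus	g__Geobacter	arsenate_reduction
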