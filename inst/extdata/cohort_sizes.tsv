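region	country	population	type	n
North Africa (Subtropical dryland)	Egypt	Barki	Indigenous	181
North Africa (Subtropical dryland)	Egypt	Saidi	Indigenous	72
North Africa (Subtropical dryland)	Egypt	Farafra	Indigenous	62
North Africa (Subtropical dryland)	Egypt	Souhagi	Indigenous	49
North Africa (Subtropical dryland)	Egypt	AHS	Indigenous	30
East Africa (Tropical Highland)	Ethiopia	Menz	Indigenous	34
East Africa (Tropical Highland)	Kenya	Red Maasai	Indigenous	45
Western Asia (Subtropical)	Cyprus	Cyprus fat tail	Indigenous	30
Western Asia (Subtropical)	Iran	Afshari	Indigenous	37
Western Asia (Subtropical)	Iran	Moghani	Indigenous	34
Western Asia (Subtropical)	Iran	Qezel	Indigenous	35
Western Asia (Subtropical)	Turkey	Karakas	Indigenous	18
Western Asia (Subtropical)	Turkey	Norduz	Indigenous	20
Western Asia (Subtropical)	Turkey	Sakiz	Indigenous	22
North/Central Europe (Temperate)	Switzerland	Bundner Oberlander	Selected	21
North/Central Europe (Temperate)	Switzerland	Swiss White Alpine	Selected	21
North/Central Europe (Temperate)	Switzerland	Valais Black Nose	Selected	21
North/Central Europe (Temperate)	Switzerland	Valais Red	Selected	21
North/Central Europe (Temperate)	Germany	East Friesian Brown	Selected	39
North/Central Europe (Temperate)	Germany	East Friesian White	Selected	9
North/Central Europe (Temperate)	England	Border Leicester	Selected	48
North/Central Europe (Temperate)	England	Dorset Horn	Selected	21
North/Central Europe (Temperate)	England	Wiltshire	Selected	23
North/Central Europe (Temperate)	Ireland	Gallway	Selected	49
North/Central Europe (Temperate)	Ireland	Irish Suffolk	Selected	55
North/Central Europe (Temperate)	Scotland	Scottish Texel	Selected	80
North/Central Europe (Temperate)	Germany	German Texel	Selected	43
North/Central Europe (Temperate)	Norway	Old Norwegian Spaelsau	Selected	15
North/Central Europe (Temperate)	Norway	Spael coloured	Selected	3
North/Central Europe (Temperate)	Finland	Finnsheep	Selected	96
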