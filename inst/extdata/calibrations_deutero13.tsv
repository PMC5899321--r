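clade_name	taxa	min_age	max_age	tail_prob
Chordata	Homo_sapiens,Branchiostoma_lanceolatum	519	581	0.025
Olfactores	Homo_sapiens,Ciona_robusta	519	581	0.025
Vertebrata	Homo_sapiens,Petromyzon_marinus	461	581	0.025
Gnathostomata	Homo_sapiens,Callorhinchus_milii	422	463	0.025
Osteichthyes	Homo_sapiens,Danio_rerio	416	422	0.025
Tetrapoda	Homo_sapiens,Xenopus_tropicalis	330	350	0.025
Amniota	Homo_sapiens,Gallus_gallus	312	330	0.025
Diapsida	Gallus_gallus,Anolis_carolinensis	256	300	0.025
Batrachia	Xenopus_tropicalis,Rana_chensinensis	200	299	0.025
Clupeocephala	Danio_rerio,Oryzias_latipes	150	165	0.025
Mammalia	Homo_sapiens,Ornithorhynchus_anatinus	163	191	0.025
Theria	Homo_sapiens,Monodelphis_domestica	124	171	0.025
Echinoidea	Strongylocentrotus_purpuratus,Eucidaris_tribuloides	255		0.025
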