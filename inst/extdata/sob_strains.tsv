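group	strain	substrate	tea	pathway	x	y	source
aerobic_thiosulfate	Thiobacillus denitrificans	thiosulfate	aerobic	calvin	0	0.710	justin_kelly
aerobic_thiosulfate	Thiobacillus denitrificans	thiosulfate	aerobic	calvin	0	0.740	alt_literature
aerobic_thiosulfate	Thiothrix CT3	thiosulfate	aerobic	calvin	0	0.738	rossetti
aerobic_thiosulfate	Beggiatoa str. D-402	thiosulfate	aerobic	calvin	0	0.761	grabovich
aerobic_thiosulfate	Thermothrix thiopara	thiosulfate	aerobic	calvin	0	0.783	brannan_caldwell
aerobic_thiosulfate	Thermithiobacillus tepidarius	thiosulfate	aerobic	calvin	0	0.804	wood_kelly
aerobic_thiosulfate	Thioalkalivibrio versutus	thiosulfate	aerobic	calvin	0	0.844	sorokin
aerobic_thiosulfate	Acidithiobacillus ferrooxidans	thiosulfate	aerobic	calvin	0	0.848	eccleston_kelly
aerobic_thiosulfate	Paracoccus versutus	thiosulfate	aerobic	calvin	0	0.853	mason
aerobic_thiosulfate	Halothiobacillus neapolitanus	thiosulfate	aerobic	calvin	0	0.859	hempfling_vishniac
aerobic_thiosulfate	Thiomicrospira thioparus	thiosulfate	aerobic	calvin	0	0.863	kelly
aerobic_thiosulfate	Sulfurimonas denitrificans	thiosulfate	aerobic	rtca	0	0.833	hoor
aerobic_thiosulfate	Acidithiobacillus thiooxidans	thiosulfate	aerobic	calvin	0	0.874	masau
aerobic_thiosulfate	Halothiobacillus halophilus	thiosulfate	aerobic	calvin	0	0.875	wood_kelly_b
aerobic_thiosulfate	Thiothrix ramosa	thiosulfate	aerobic	calvin	0	0.875	odintsova
aerobic_thiosulfate	Thioalkalispira microaerophila	thiosulfate	aerobic	calvin	0	0.884	sorokin_b
aerobic_thiosulfate	Thioalkalimicrobium aerophilum	thiosulfate	aerobic	calvin	0	0.891	sorokin_c
aerobic_thiosulfate	Thiomicrospira halophila	thiosulfate	aerobic	calvin	0	0.891	sorokin_d
aerobic_thiosulfate	Thioalkalibacter halophilus	thiosulfate	aerobic	calvin	0	0.891	banciu
aerobic_thiosulfate	Thiobacillus thioparus	thiosulfate	aerobic	calvin	0	0.898	smith_kelly
aerobic_thiosulfate	Thioclava pacifica	thiosulfate	aerobic	calvin	0	0.913	sorokin_e
aerobic_thiosulfate	Thioalkalimicrobium sibericum	thiosulfate	aerobic	calvin	0	0.916	sorokin_f
aerobic_thiosulfate	Thiomicrospira sp. L-12	thiosulfate	aerobic	calvin	0.2	0.921	ruby_jannasch
denitrifying_thiosulfate	Thiobacillus denitrificans	thiosulfate	denitrification	calvin	0	0.775	justin_kelly
denitrifying_thiosulfate	Thiobacillus denitrificans	thiosulfate	denitrification	calvin	0	0.812	schedel
denitrifying_thiosulfate	Sulfurimonas hongkongensis	thiosulfate	denitrification	rtca	0	0.852	cai
denitrifying_thiosulfate	Sulfurimonas gotlandica	thiosulfate	denitrification	rtca	0	0.875	bruckner
denitrifying_thiosulfate	Sulfurimonas gotlandica-like epsilonproteobacterium	thiosulfate	denitrification	rtca	0	0.887	brettar
denitrifying_thiosulfate	Sulfurimonas denitrificans	thiosulfate	denitrification	rtca	0	0.902	sievert
aerobic_sulfide	Riftia pachyptila symbionts	sulfide	aerobic	calvin	-1.12	0.375	girguis
aerobic_sulfide	Solemya reidi symbionts	sulfide	aerobic	calvin	0.17	0.429	anderson
aerobic_sulfide	Riftia pachyptila symbionts	sulfide	aerobic	calvin	0.33	0.500	girguis_childress
aerobic_sulfide	Beggiatoa str. MS-81-1c	sulfide	aerobic	calvin	0.05	0.641	hagen_nelson
aerobic_sulfide	Ridgeia piscesae symbionts	sulfide	aerobic	calvin	0	0.714	nyholm
aerobic_sulfide	Thermithiobacillus tepidarius	sulfide	aerobic	calvin	0	0.808	wood_kelly
aerobic_sulfide	Beggiatoa str. MS-81-6	sulfide	aerobic	calvin	0	0.825	hagen_nelson
aerobic_sulfide	Halothiobacillus neapolitanus	sulfide	aerobic	calvin	0	0.859	kelly_b
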