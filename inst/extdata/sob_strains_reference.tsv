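group	strain	y	eps_I_pct	eps_II_pct	eps_so_min_pct	co2_tea
aerobic_thiosulfate	Thiobacillus denitrificans	0.710	6.39	17.59	22.76	0.41
aerobic_thiosulfate	Thiobacillus denitrificans	0.740	5.50	15.13	19.58	0.35
aerobic_thiosulfate	Thiothrix CT3	0.738	5.55	15.29	19.78	0.36
aerobic_thiosulfate	Beggiatoa str. D-402	0.761	4.91	13.52	17.50	0.31
aerobic_thiosulfate	Thermothrix thiopara	0.783	4.34	11.93	15.44	0.28
aerobic_thiosulfate	Thermithiobacillus tepidarius	0.804	3.81	10.50	13.58	0.24
aerobic_thiosulfate	Thioalkalivibrio versutus	0.844	2.90	7.96	10.30	0.18
aerobic_thiosulfate	Acidithiobacillus ferrooxidans	0.848	2.80	7.72	9.99	0.18
aerobic_thiosulfate	Paracoccus versutus	0.853	2.70	7.42	9.60	0.17
aerobic_thiosulfate	Halothiobacillus neapolitanus	0.859	2.57	7.07	9.15	0.16
aerobic_thiosulfate	Thiomicrospira thioparus	0.863	2.48	6.84	8.85	0.16
aerobic_thiosulfate	Sulfurimonas denitrificans	0.833	3.13	7.99	8.18	0.20
aerobic_thiosulfate	Acidithiobacillus thiooxidans	0.874	2.26	6.21	8.03	0.14
aerobic_thiosulfate	Halothiobacillus halophilus	0.875	2.23	6.15	7.96	0.14
aerobic_thiosulfate	Thiothrix ramosa	0.875	2.23	6.15	7.96	0.14
aerobic_thiosulfate	Thioalkalispira microaerophila	0.884	2.05	5.65	7.31	0.13
aerobic_thiosulfate	Thioalkalimicrobium aerophilum	0.891	1.91	5.27	6.82	0.12
aerobic_thiosulfate	Thiomicrospira halophila	0.891	1.91	5.27	6.82	0.12
aerobic_thiosulfate	Thioalkalibacter halophilus	0.891	1.91	5.27	6.82	0.12
aerobic_thiosulfate	Thiobacillus thioparus	0.898	1.78	4.89	6.33	0.11
aerobic_thiosulfate	Thioclava pacifica	0.913	1.49	4.10	5.31	0.10
aerobic_thiosulfate	Thioalkalimicrobium sibericum	0.916	1.43	3.95	5.11	0.09
aerobic_thiosulfate	Thiomicrospira sp. L-12	0.921	1.29	3.91	4.99	0.09
denitrifying_thiosulfate	Thiobacillus denitrificans	0.775	5.15	14.18	18.35	0.36
denitrifying_thiosulfate	Thiobacillus denitrificans	0.812	4.11	11.31	14.63	0.29
denitrifying_thiosulfate	Sulfurimonas hongkongensis	0.852	3.08	7.85	8.04	0.22
denitrifying_thiosulfate	Sulfurimonas gotlandica	0.875	2.53	6.45	6.61	0.18
denitrifying_thiosulfate	Sulfurimonas gotlandica-like epsilonproteobacterium	0.887	2.26	5.76	5.89	0.16
denitrifying_thiosulfate	Sulfurimonas denitrificans	0.902	1.93	4.91	5.03	0.14
aerobic_sulfide	Riftia pachyptila symbionts	0.375	30.52	77.27	98.86	1.67
aerobic_sulfide	Solemya reidi symbionts	0.429	22.83	59.80	76.87	1.33
aerobic_sulfide	Riftia pachyptila symbionts	0.500	16.80	44.50	57.29	1.00
aerobic_sulfide	Beggiatoa str. MS-81-1c	0.641	9.72	25.30	32.50	0.56
aerobic_sulfide	Ridgeia piscesae symbionts	0.714	6.98	18.13	23.29	0.40
aerobic_sulfide	Thermithiobacillus tepidarius	0.808	4.14	10.76	13.81	0.24
aerobic_sulfide	Beggiatoa str. MS-81-6	0.825	3.70	9.60	12.33	0.21
aerobic_sulfide	Halothiobacillus neapolitanus	0.859	2.86	7.43	9.54	0.16
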