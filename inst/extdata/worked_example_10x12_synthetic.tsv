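# worked_example_10x12_synthetic.tsv
# SYNTHETIC worked-example network -- not field data.
# Generated once with the bipartmod planted-partition generator:
#   plant_modules(synthetic_spec(n_rows=10, n_cols=12, n_modules=4,
#                                nb_size=2.5, nb_mean=4, seed=42))
#   then rewire_noise(noise=0.25, seed=43); generic species-style labels.
# It stands in for a published plant-pollinator visitation matrix that
# cannot be redistributed with the package.
	insect_01	insect_02	insect_03	insect_04	insect_05	insect_06	insect_07	insect_08	insect_09	insect_10	insect_11	insect_12
plant_01	1	6	0	0	0	0	0	0	0	0	0	0
plant_02	0	12	0	0	0	0	0	0	0	0	0	0
plant_03	5	0	0	0	0	0	0	0	0	0	0	0
plant_04	0	3	0	0	0	12	0	0	0	0	0	0
plant_05	0	4	0	0	0	0	0	0	0	0	0	0
plant_06	0	0	3	0	1	0	0	0	0	0	4	0
plant_07	9	8	0	2	0	0	0	0	7	0	0	1
plant_08	0	0	0	0	0	3	2	1	0	0	0	0
plant_09	0	0	0	0	0	0	0	0	0	3	4	5
plant_10	0	0	0	0	0	0	0	0	2	2	0	0
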