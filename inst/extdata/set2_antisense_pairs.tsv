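gene_id	sense_log2fc	sense_pvalue	feature_id	antisense_log2fc	antisense_pvalue
FIG2	1.22	6.47e-34	chrIII_268287_269650	6.08	1.25e-54
FLO10	1.26	2.11e-22	chrXI_646150_649088	4.35	4.98e-191
GTT2	1.08	1.94e-17	chrXII_21160_21867	2.33	1.90e-14
HEF3	1.37	1.66e-35	chrXIV_607466_608421	3.70	6.04e-36
SFL1	1.03	2.06e-14	chrXV_587861_589241	2.19	1.84e-24
PCA1	1.48	6.05e-51	chrII_792527_796498	4.41	1.33e-140
AVT2	-1.03	2.63e-14	chrV_30251_31501	2.97	2.74e-30
ADE5,7	-1.23	5.40e-37	chrVII_56171_57183	1.96	3.14e-10
CLB6	-1.04	6.77e-05	chrVII_706126_706667	2.60	8.40e-12
CLB6	-1.04	6.77e-05	chrVII_705368_706105	2.50	6.52e-15
YJL213W	-1.20	1.67e-28	chrX_31954_33105	2.25	8.46e-12
SRY1	-1.91	1.18e-67	chrXI_17659_18490	1.87	1.22e-14
YLR124W	-3.34	7.80e-07	chrXII_391411_393246	1.60	5.78e-27
HXT2	-1.07	1.81e-08	chrXIII_288228_289458	1.98	2.45e-14
INP2	-1.17	4.04e-17	chrXIII_584350_585354	2.83	6.67e-25
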