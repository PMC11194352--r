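# Reference summary table of 22 published average-methylation regions
# (group main-effect track). median_* are median pairwise group contrasts
# (P-R, R-M, P-M; M-units). The source table prints no per-contrast
# consistency percentages, only that each retained region had at least one
# fully consistent pairwise contrast; that unanimous contrast is encoded
# (synthetically) on the P-M column, the other contrasts as 0.5.
region_id	chrom	start	stop	n_probes	sidak_p	leading_probe	consistency_pvr	consistency_rvm	consistency_pvm	median_pvr	median_rvm	median_pvm
mDMR1	chr1	180922636	180923341	4	1.38e-05	cg00579423	0.5	0.5	1.0	0.09	0.37	0.46
mDMR2	chr10	99338056	99338241	4	1.75e-04	cg27469738	0.5	0.5	1.0	-0.11	0.26	0.17
mDMR3	chr10	52008360	52008906	4	6.45e-03	cg24123634	0.5	0.5	1.0	-0.07	-0.02	-0.11
mDMR4	chr12	2943902	2944481	4	7.06e-03	cg02852959	0.5	0.5	1.0	-0.15	0.19	0.04
mDMR5	chr12	75784855	75785098	6	7.59e-03	cg12351126	0.5	0.5	1.0	0.10	0.24	0.34
mDMR6	chr12	51566379	51567113	7	1.24e-02	cg19016289	0.5	0.5	1.0	0.05	0.15	0.20
mDMR7	chr1	1289835	1290713	6	1.61e-02	cg07284273	0.5	0.5	1.0	-0.16	0.33	0.15
mDMR8	chr15	72766637	72767333	4	1.93e-02	cg26880891	0.5	0.5	1.0	0.09	0.02	0.14
mDMR9	chr19	45206843	45207560	4	2.78e-02	cg24091949	0.5	0.5	1.0	-0.09	-0.04	-0.13
mDMR10	chr19	2250901	2251068	4	2.83e-02	cg23218559	0.5	0.5	1.0	-0.18	0.38	0.21
mDMR11	chr18	7567426	7568266	5	3.44e-02	cg05870479	0.5	0.5	1.0	0.09	0.04	0.11
mDMR12	chr15	85524778	85525674	4	4.02e-02	cg02839273	0.5	0.5	1.0	0.05	0.05	0.13
mDMR13	chr2	85765644	85766105	4	4.39e-02	cg06978067	0.5	0.5	1.0	0.08	0.05	0.13
mDMR14	chr19	48048129	48049234	4	4.90e-02	cg22341310	0.5	0.5	1.0	-0.12	0.17	0.06
mDMR15	chr4	4861683	4862241	4	5.94e-02	cg11930592	0.5	0.5	1.0	0.12	-0.04	0.08
mDMR16	chr11	598325	599091	5	7.14e-02	cg12921473	0.5	0.5	1.0	-0.06	-0.05	-0.10
mDMR17	chr5	101119084	101119767	4	7.67e-02	cg12197752	0.5	0.5	1.0	0.09	0.18	0.29
mDMR18	chr13	42031761	42032737	4	8.16e-02	cg18495682	0.5	0.5	1.0	0.06	0.02	0.09
mDMR19	chr3	38206610	38207525	4	8.20e-02	cg19728055	0.5	0.5	1.0	0.07	0.05	0.11
mDMR20	chr10	14372431	14372914	5	8.45e-02	cg05755354	0.5	0.5	1.0	-0.16	-0.02	-0.18
mDMR21	chr8	145550361	145551157	5	8.72e-02	cg11127482	0.5	0.5	1.0	0.06	0.04	0.11
mDMR22	chr11	128693473	128694916	9	9.44e-02	cg15509024	0.5	0.5	1.0	-0.12	-0.09	-0.18
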