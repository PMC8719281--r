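# Synthetic planted effect-size vector used by the cohort generator defaults.
phenotype	effect
thk_bankssts	-0.28
thk_caudalanteriorcingulate	-0.265
thk_caudalmiddlefrontal	-0.25
thk_cuneus	-0.23500000000000001
thk_entorhinal	-0.22000000000000003
thk_frontalpole	-0.20500000000000002
thk_fusiform	-0.19
thk_inferiorparietal	-0.17500000000000002
thk_inferiortemporal	-0.16000000000000003
thk_insula	-0.14500000000000002
thk_isthmuscingulate	-0.13
thk_lateraloccipital	-0.11500000000000002
thk_lateralorbitofrontal	-0.1
thk_lingual	-0.08500000000000002
thk_medialorbitofrontal	-0.07
thk_middletemporal	-0.05500000000000002
thk_paracentral	-0.04000000000000001
thk_parahippocampal	-0.025000000000000022
thk_parsopercularis	-0.010000000000000009
thk_parsorbitalis	0.0050000000000000044
thk_parstriangularis	0.020000000000000018
thk_pericalcarine	0.034999999999999976
thk_postcentral	0.04999999999999999
thk_posteriorcingulate	0.065
thk_precentral	0.08000000000000002
thk_precuneus	0.09500000000000003
thk_rostralanteriorcingulate	0.10999999999999999
thk_rostralmiddlefrontal	0.125
thk_superiorfrontal	0.14
thk_superiorparietal	0.15500000000000003
thk_superiortemporal	0.16999999999999998
thk_supramarginal	0.185
thk_transversetemporal	0.2
fa_ACR	-0.3
fa_ALIC	-0.29043478260869565
fa_BCC	-0.2808695652173913
fa_CC	-0.2713043478260869
fa_CGC	-0.2617391304347826
fa_CGH	-0.25217391304347825
fa_CR	-0.2426086956521739
fa_CST	-0.23304347826086957
fa_EC	-0.2234782608695652
fa_FX	-0.21391304347826084
fa_FXST	-0.2043478260869565
fa_GCC	-0.19478260869565217
fa_IC	-0.18521739130434783
fa_IFO	-0.17565217391304347
fa_PCR	-0.16608695652173913
fa_PLIC	-0.15652173913043477
fa_PTR	-0.14695652173913043
fa_RLIC	-0.1373913043478261
fa_SCC	-0.12782608695652173
fa_SCR	-0.11826086956521739
fa_SFO	-0.10869565217391303
fa_SLF	-0.09913043478260869
fa_SS	-0.08956521739130435
fa_UNC	-0.08
vol_thalamus	-0.12
vol_caudate	-0.09333333333333332
vol_putamen	-0.06666666666666665
vol_pallidum	-0.039999999999999994
vol_hippocampus	-0.013333333333333322
vol_amygdala	0.013333333333333336
vol_accumbens	0.04
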