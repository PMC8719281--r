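# Template meta-analytic effect-size vector: replace the zero placeholders
# with published signed case-control effects (deficits negative).
phenotype	effect
thk_bankssts	0
thk_caudalanteriorcingulate	0
thk_caudalmiddlefrontal	0
thk_cuneus	0
thk_entorhinal	0
thk_frontalpole	0
thk_fusiform	0
thk_inferiorparietal	0
thk_inferiortemporal	0
thk_insula	0
thk_isthmuscingulate	0
thk_lateraloccipital	0
thk_lateralorbitofrontal	0
thk_lingual	0
thk_medialorbitofrontal	0
thk_middletemporal	0
thk_paracentral	0
thk_parahippocampal	0
thk_parsopercularis	0
thk_parsorbitalis	0
thk_parstriangularis	0
thk_pericalcarine	0
thk_postcentral	0
thk_posteriorcingulate	0
thk_precentral	0
thk_precuneus	0
thk_rostralanteriorcingulate	0
thk_rostralmiddlefrontal	0
thk_superiorfrontal	0
thk_superiorparietal	0
thk_superiortemporal	0
thk_supramarginal	0
thk_transversetemporal	0
fa_ACR	0
fa_ALIC	0
fa_BCC	0
fa_CC	0
fa_CGC	0
fa_CGH	0
fa_CR	0
fa_CST	0
fa_EC	0
fa_FX	0
fa_FXST	0
fa_GCC	0
fa_IC	0
fa_IFO	0
fa_PCR	0
fa_PLIC	0
fa_PTR	0
fa_RLIC	0
fa_SCC	0
fa_SCR	0
fa_SFO	0
fa_SLF	0
fa_SS	0
fa_UNC	0
vol_thalamus	0
vol_caudate	0
vol_putamen	0
vol_pallidum	0
vol_hippocampus	0
vol_amygdala	0
vol_accumbens	0
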