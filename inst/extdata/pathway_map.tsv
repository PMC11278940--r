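gene_family	pathway
# nitrification: ammonia/methane monooxygenase, hydroxylamine oxidoreductase,
# nitrite oxidoreductase
amoA	NITRIFICATION
amoB	NITRIFICATION
amoC	NITRIFICATION
pmoA	NITRIFICATION
pmoB	NITRIFICATION
pmoC	NITRIFICATION
hao	NITRIFICATION
nxrA	NITRIFICATION
nxrB	NITRIFICATION
# nitrogen fixation: nitrogenase structural genes and alternative nitrogenases
nifH	NITROGEN_FIXATION
nifD	NITROGEN_FIXATION
nifK	NITROGEN_FIXATION
anfG	NITROGEN_FIXATION
vnfG	NITROGEN_FIXATION
# denitrification: nitrite -> NO -> N2O -> N2
nirK	DENITRIFICATION
nirS	DENITRIFICATION
norB	DENITRIFICATION
norC	DENITRIFICATION
nosZ	DENITRIFICATION
# dissimilatory nitrate -> nitrite: membrane-bound and periplasmic reductases
narG	DISSIM_NITRATE_TO_NITRITE
narH	DISSIM_NITRATE_TO_NITRITE
narI	DISSIM_NITRATE_TO_NITRITE
napA	DISSIM_NITRATE_TO_NITRITE
napB	DISSIM_NITRATE_TO_NITRITE
# dissimilatory nitrite -> ammonia (DNRA)
nirB	DISSIM_NITRITE_TO_AMMONIA
nirD	DISSIM_NITRITE_TO_AMMONIA
nrfA	DISSIM_NITRITE_TO_AMMONIA
nrfH	DISSIM_NITRITE_TO_AMMONIA
# assimilatory nitrate reduction
nasA	ASSIM_NITRATE_REDUCTION
nasB	ASSIM_NITRATE_REDUCTION
narB	ASSIM_NITRATE_REDUCTION
nirA	ASSIM_NITRATE_REDUCTION
NR	ASSIM_NITRATE_REDUCTION
# ammonia assimilation: GS/GOGAT, GDH, urease
glnA	AMMONIA_ASSIMILATION
gltB	AMMONIA_ASSIMILATION
gltD	AMMONIA_ASSIMILATION
gdhA	AMMONIA_ASSIMILATION
ureA	AMMONIA_ASSIMILATION
ureB	AMMONIA_ASSIMILATION
ureC	AMMONIA_ASSIMILATION
# anammox: hydrazine synthase / dehydrogenase
hzsA	ANAMMOX
hzsB	ANAMMOX
hzsC	ANAMMOX
hdh	ANAMMOX
hzo	ANAMMOX
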