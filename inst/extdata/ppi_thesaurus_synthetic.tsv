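# Default PPI descriptor vocabulary: 14 stemmed interaction terms plus
# the 9 experimental-method names most used to evidence protein-protein
# interactions (23 concepts in total).
# SYNTHETIC RECONSTRUCTION: the original curated list is not
# redistributable; this file completes the published exemplar terms
# (bind, interact, associate, complex, ...) to the documented 14 + 9
# layout. Single-token stems match word prefixes; stems containing a
# space (and multi-word labels) match as exact token phrases.
concept_id	label	stems	category
PPI:bind	bind	bind|bound	interaction_term
PPI:interact	interact	interact	interaction_term
PPI:associate	associate	associat	interaction_term
PPI:complex	complex	complex	interaction_term
PPI:dimerize	dimerize	dimeriz|dimeris	interaction_term
PPI:heterodimer	heterodimer	heterodimer	interaction_term
PPI:homodimer	homodimer	homodimer	interaction_term
PPI:oligomerize	oligomerize	oligomer	interaction_term
PPI:recruit	recruit	recruit	interaction_term
PPI:dock	dock	dock	interaction_term
PPI:tether	tether	tether	interaction_term
PPI:colocalize	colocalize	colocaliz|colocalis	interaction_term
PPI:crosslink	crosslink	crosslink	interaction_term
PPI:ligand	ligand	ligand	interaction_term
PPI:two_hybrid	two hybrid	two hybrid	experimental_method
PPI:coimmunoprecipitation	coimmunoprecipitation	coimmunoprecipitat|immunoprecipitat	experimental_method
PPI:pull_down	pull down	pulldown	experimental_method
PPI:affinity_chromatography	affinity chromatography	affinity chromatography	experimental_method
PPI:surface_plasmon_resonance	surface plasmon resonance	surface plasmon	experimental_method
PPI:xray_crystallography	x-ray crystallography	crystallograph	experimental_method
PPI:mass_spectrometry	mass spectrometry	mass spectrometry	experimental_method
PPI:fret	fluorescence resonance energy transfer	fret	experimental_method
PPI:far_western	far western blot	far western	experimental_method
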