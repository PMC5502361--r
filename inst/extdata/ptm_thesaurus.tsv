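# Default PTM descriptor vocabulary: the 16 most frequent
# post-translational modification types. Single-token stems match word
# prefixes (e.g. "phosphorylat" covers phosphorylated, phosphorylates,
# phosphorylating, phosphorylation); stems are pipe-separated.
concept_id	label	stems	category
PTM:phosphorylation	phosphorylation	phosphorylat	ptm_type
PTM:dephosphorylation	dephosphorylation	dephosphorylat	ptm_type
PTM:methylation	methylation	methylat	ptm_type
PTM:glycosylation	glycosylation	glycosylat	ptm_type
PTM:nitrosylation	nitrosylation	nitrosylat	ptm_type
PTM:palmitoylation	palmitoylation	palmitoylat	ptm_type
PTM:deubiquitination	deubiquitination	deubiquitinat|deubiquitylat	ptm_type
PTM:polyadp_ribosylation	polyADP-ribosylation	ribosylat	ptm_type
PTM:acetylation	acetylation	acetylat	ptm_type
PTM:deacetylation	deacetylation	deacetylat	ptm_type
PTM:desumoylation	desumoylation	desumoylat	ptm_type
PTM:sumoylation	sumoylation	sumoylat	ptm_type
PTM:myristoylation	myristoylation	myristoylat	ptm_type
PTM:farnesylation	farnesylation	farnesylat	ptm_type
PTM:ubiquitination	ubiquitination	ubiquitinat|ubiquitylat	ptm_type
PTM:cleavage	protein cleavage	cleav	ptm_type
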