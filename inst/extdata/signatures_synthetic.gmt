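CBPEGS	partial editable placeholder: de novo cholesterol biosynthesis pathway enzyme genes; only the two widely cited members are listed, extend with the remaining four for a full 6-gene set	SQLE	DHCR7
NAMJOU_NODES	liver transcriptional driver nodes reported for NAFLD GWAS-associated genes	PPARG	FLI1	SPI1	CEBPA
GOVAERE	empty editable placeholder: 25-gene NAFLD severity signature; populate from its published supplement	FILL_ME
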