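# Miniature taxonomy-to-function rule set for rhizosphere soil bacteria.
# Flat-file dialect: a function header starts at column 0 (name, then free
# metadata); each indented line carries one taxon pattern; "add_group:NAME"
# imports the clauses of a previously defined function. "*" matches any
# substring of a rank name or of the full semicolon lineage path.

aerobic_chemoheterotrophy	elements:C	electron_acceptor:O2
	*Sphingomonas*
	*Pseudarthrobacter*
	*Hyphomicrobiaceae*
	*Devosia*
	*Baekduia*
fermentation	elements:C	electron_acceptor:organic
	*Clostridium*
	*Lactobacillus*
	*Streptosporangium*
chemoheterotrophy	elements:C
	add_group:aerobic_chemoheterotrophy
	add_group:fermentation
	*Burkholderiales*
nitrification	elements:N
	*Nitrospira*
	*Nitrosomonas*
	*Nitrosospira*
nitrogen_fixation	elements:N
	*Bradyrhizobium*
	*Rhizobium*
	*Azotobacter*
denitrification	elements:N
	*Bradyrhizobium*
	*Paracoccus*
	*Pseudomonas stutzeri*
ureolysis	elements:N
	*Sporosarcina*
	*Proteus*
methylotrophy	elements:C
	*Methylobacterium*
	*Hyphomicrobium*
methanol_oxidation	elements:C
	*Methylobacterium*
aromatic_compound_degradation	elements:C
	*Bradyrhizobium*
	*Sphingomonas*
chitinolysis	elements:C
	*Streptomyces*
	*Chitinophaga*
cellulolysis	elements:C
	*Cellulomonas*
	*Fibrobacter*
photoheterotrophy	elements:C
	*Rhodoplanes*
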