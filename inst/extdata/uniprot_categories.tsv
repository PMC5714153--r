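# Starter descriptor table for the dataset category scheme: the 11 UniProt
# curator categories plus Clinical trial. One class<TAB>descriptor per line;
# descriptors are stemmed on load, so surface phrases are fine. Extend freely.
Expression	expression
Expression	gene expression
Expression	tissue specificity
Expression	induction
Expression	expression profiling
Expression	microarray
Expression	rna seq
Family & Domains	domain
Family & Domains	protein family
Family & Domains	motif
Family & Domains	repeat
Family & Domains	similarity
Function	function
Function	catalytic activity
Function	enzyme regulation
Function	cofactor
Function	pathway
Interaction	interaction
Interaction	protein protein interaction
Interaction	binding
Interaction	subunit
Names	nomenclature
Names	gene name
Names	synonym
Pathology & Biotech	disease
Pathology & Biotech	disruption phenotype
Pathology & Biotech	mutagenesis
Pathology & Biotech	allergen
Pathology & Biotech	biotechnology
Pathology & Biotech	pharmaceutical
PTM/processing	post translational modification
PTM/processing	phosphorylation
PTM/processing	glycosylation
PTM/processing	ubiquitination
PTM/processing	signal peptide
PTM/processing	proteolytic cleavage
Sequences	sequence
Sequences	protein sequence
Sequences	nucleotide sequence
Sequences	genome sequencing
Sequences	sequence variant
Sequences	alternative splicing
Structure	structure
Structure	crystal structure
Structure	x ray crystallography
Structure	nmr spectroscopy
Structure	secondary structure
Subcellular location	subcellular location
Subcellular location	membrane
Subcellular location	secreted
Subcellular location	nucleus
Subcellular location	mitochondrion
Unclassified	miscellaneous
Unclassified	uncharacterized
Clinical trial	clinical trial
Clinical trial	clinical study
Clinical trial	randomized controlled trial
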