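keyword	category
tail sheath	tail_sheath
sheath protein	tail_sheath
tape measure	tape_measure
large terminase	terminase_large
terminase large	terminase_large
terminase, large	terminase_large
small terminase	terminase_small
terminase small	terminase_small
terminase, small	terminase_small
terminase	terminase_large
portal	portal
baseplate	baseplate
base plate	baseplate
major capsid	head
capsid	head
head protein	head
major head	head
head-tail	neck
head closure	neck
neck	neck
tail fiber	tail
tail fibre	tail
tail assembly	tail
tail protein	tail
minor tail	tail
major tail	tail
tail terminator	tail
tail spike	tail
integrase	integrase
site-specific recombinase	integrase
tyrosine recombinase	integrase
serine recombinase	integrase
transposase	transposase
endolysin	lysis
lysozyme	lysis
lysin	lysis
spanin	lysis
holin	lysis
lysis	lysis
dna polymerase	nucleic_acid_metabolism
rna polymerase	nucleic_acid_metabolism
polymerase	nucleic_acid_metabolism
helicase	nucleic_acid_metabolism
primase	nucleic_acid_metabolism
ligase	nucleic_acid_metabolism
exonuclease	nucleic_acid_metabolism
endonuclease	nucleic_acid_metabolism
nuclease	nucleic_acid_metabolism
ribonucleotide reductase	nucleic_acid_metabolism
single-stranded dna binding	nucleic_acid_metabolism
single strand dna binding	nucleic_acid_metabolism
dna methyltransferase	nucleic_acid_metabolism
recombination protein	nucleic_acid_metabolism
replication protein	nucleic_acid_metabolism
antirepressor	regulation
repressor	regulation
transcriptional regulator	regulation
transcription factor	regulation
regulatory protein	regulation
anti-sigma	regulation
sigma factor	regulation
cro protein	regulation
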