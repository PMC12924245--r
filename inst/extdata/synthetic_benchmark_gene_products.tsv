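region_id	product
Bath-R1	integrase
Bath-R1	repressor protein CI
Bath-R1	DNA polymerase
Bath-R1	replicative DNA helicase
Bath-R1	large terminase subunit
Bath-R1	small terminase subunit
Bath-R1	portal protein
Bath-R1	major capsid protein
Bath-R1	head closure protein
Bath-R1	tail length tape measure protein
Bath-R1	major tail protein
Bath-R1	endolysin
Bath-R1	hypothetical protein
Bath-R2	transposase
Bath-R2	transcriptional regulator
Bath-R2	DNA polymerase
Bath-R2	replicative DNA helicase
Bath-R2	large terminase subunit
Bath-R2	small terminase subunit
Bath-R2	portal protein
Bath-R2	major capsid protein
Bath-R2	neck protein
Bath-R2	tail sheath protein
Bath-R2	baseplate protein
Bath-R2	major tail protein
Bath-R2	endolysin
Bath-R2	hypothetical protein
KN2-R1	integrase
KN2-R1	repressor protein CI
KN2-R1	DNA polymerase
KN2-R1	replicative DNA helicase
KN2-R1	large terminase subunit
KN2-R1	small terminase subunit
KN2-R1	portal protein
KN2-R1	major capsid protein
KN2-R1	head closure protein
KN2-R1	tail length tape measure protein
KN2-R1	major tail protein
KN2-R1	endolysin
KN2-R1	hypothetical protein
KN2-R2	DNA polymerase
KN2-R2	replicative DNA helicase
KN2-R2	large terminase subunit
KN2-R2	small terminase subunit
KN2-R2	portal protein
KN2-R2	major capsid protein
KN2-R2	head closure protein
KN2-R2	tail length tape measure protein
KN2-R2	major tail protein
KN2-R2	endolysin
KN2-R2	hypothetical protein
IO1-R1	transposase
IO1-R1	transcriptional regulator
IO1-R1	DNA polymerase
IO1-R1	replicative DNA helicase
IO1-R1	large terminase subunit
IO1-R1	small terminase subunit
IO1-R1	portal protein
IO1-R1	major capsid protein
IO1-R1	neck protein
IO1-R1	tail sheath protein
IO1-R1	baseplate protein
IO1-R1	major tail protein
IO1-R1	endolysin
IO1-R1	hypothetical protein
McNor-R1	repressor protein CI
McNor-R1	tail length tape measure protein
McNor-R1	major tail protein
McNor-R1	minor tail protein
McNor-R1	endolysin
McNor-R1	hypothetical protein
McNor-R2	integrase
McNor-R2	repressor protein CI
McNor-R2	DNA polymerase
McNor-R2	replicative DNA helicase
McNor-R2	large terminase subunit
McNor-R2	small terminase subunit
McNor-R2	portal protein
McNor-R2	major capsid protein
McNor-R2	head closure protein
McNor-R2	tail length tape measure protein
McNor-R2	major tail protein
McNor-R2	endolysin
McNor-R2	hypothetical protein
McNor-R3	integrase
McNor-R3	repressor protein CI
McNor-R3	DNA polymerase
McNor-R3	replicative DNA helicase
McNor-R3	large terminase subunit
McNor-R3	small terminase subunit
McNor-R3	portal protein
McNor-R3	major capsid protein
McNor-R3	head closure protein
McNor-R3	tail length tape measure protein
McNor-R3	major tail protein
McNor-R3	endolysin
McNor-R3	hypothetical protein
16-5-R1	integrase
16-5-R1	repressor protein CI
16-5-R1	DNA polymerase
16-5-R1	replicative DNA helicase
16-5-R1	large terminase subunit
16-5-R1	small terminase subunit
16-5-R1	portal protein
16-5-R1	major capsid protein
16-5-R1	head closure protein
16-5-R1	tail length tape measure protein
16-5-R1	major tail protein
16-5-R1	endolysin
16-5-R1	hypothetical protein
16-5-R2	transposase
16-5-R2	repressor protein CI
16-5-R2	DNA polymerase
16-5-R2	replicative DNA helicase
16-5-R2	DNA ligase
16-5-R2	large terminase subunit
16-5-R2	small terminase subunit
16-5-R2	portal protein
16-5-R2	major capsid protein
16-5-R2	neck protein
16-5-R2	tail length tape measure protein
16-5-R2	major tail protein
16-5-R2	Rz-like spanin
16-5-R2	endolysin
16-5-R3	integrase
16-5-R3	repressor protein CI
16-5-R3	DNA polymerase
16-5-R3	replicative DNA helicase
16-5-R3	large terminase subunit
16-5-R3	small terminase subunit
16-5-R3	portal protein
16-5-R3	major capsid protein
16-5-R3	head closure protein
16-5-R3	tail length tape measure protein
16-5-R3	major tail protein
16-5-R3	endolysin
16-5-R3	hypothetical protein
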