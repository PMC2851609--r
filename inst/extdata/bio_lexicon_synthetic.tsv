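protein	120000
cell	95000
gene	15000
subunit	20000
acid	18000
factor	12000
genes	5000
receptor	4000
channel	9000
complex	2500
activity	1500
binding	800
pathway	600
kinase	300
domain	150
enzyme	90
expression	75
membrane	60
phosphatase	45
transcription	30
ligand	25
promoter	12
cytokine	8
homolog	6
repeats	4
isoform	2
interleukin	1
necrosis	1
tumor	40	gn
insulin	9500	pr
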