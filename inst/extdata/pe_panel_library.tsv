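compound_id	name	compound_class	kegg_id	neutral_mass
HMDB0002282	2-(acetylamino)-1,5-anhydro-2-deoxy-4-O-b-D-galactopyranosyl-D-arabino-Hex-1-enitol	O-glycosyl compounds	NA	365.13
HMDB0003689	Neuroprotectin D1	Very long-chain fatty acids	NA	360.23
HMDB0013327	Dodecanedioylcarnitine	Tricarboxylic acids	NA	373.25
HMDB0006766	Estriol-16-Glucuronide	Steroids and steroid derivatives	C05504	464.20
HMDB0004220	Biotinyl-5'-AMP	Carboxylic acids and derivatives	C05921	573.14
HMDB0001445	N-Acetyl-D-glucosaminyldiphosphodolichol	Prenol lipids	C04500	587.23
HMDB0006557	ADP-glucose	Purine nucleotide sugars	C00498	589.08
HMDB0011764	Cer(d18:0/20:0)	Ceramides	NA	595.59
HMDB0000381	Allolithocholic acid	Bile acids	NA	376.30
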