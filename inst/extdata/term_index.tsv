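ontology	term_id	preferred_label	synonyms
DOID	DOID:9253	gastrointestinal stromal tumor	GIST
DOID	DOID:526	human immunodeficiency virus infectious disease	HIV|HIV infection|HIV disease
DOID	DOID:3907	lung squamous cell carcinoma	squamous cell carcinoma of lung|epidermoid cell lung carcinoma
DOID	DOID:1909	melanoma	malignant melanoma
DOID	DOID:1612	breast cancer	breast tumor|mammary cancer
DOID	DOID:9351	diabetes mellitus	diabetes
DOID	DOID:2841	asthma	bronchial hyperreactivity
DOID	DOID:9256	colorectal cancer	colorectal carcinoma
DOID	DOID:8469	influenza	flu
DOID	DOID:1324	lung cancer	cancer of lung
DOID	DOID:10652	Alzheimer's disease	Alzheimer disease|AD
DOID	DOID:14330	Parkinson's disease	Parkinson disease|paralysis agitans
NCBITaxon	NCBITaxon:9606	Homo sapiens	human|man
NCBITaxon	NCBITaxon:10090	Mus musculus	house mouse|mouse
NCBITaxon	NCBITaxon:562	Escherichia coli	E. coli
NCBITaxon	NCBITaxon:3702	Arabidopsis thaliana	thale cress
NCBITaxon	NCBITaxon:4932	Saccharomyces cerevisiae	baker's yeast
NCBITaxon	NCBITaxon:7955	Danio rerio	zebrafish|leopard danio
NCBITaxon	NCBITaxon:7227	Drosophila melanogaster	fruit fly
NCBITaxon	NCBITaxon:10116	Rattus norvegicus	Norway rat|brown rat
NCBITaxon	NCBITaxon:9913	Bos taurus	cattle|cow
NCBITaxon	NCBITaxon:9823	Sus scrofa	pig|wild boar
NCBITaxon	NCBITaxon:9031	Gallus gallus	chicken
NCBITaxon	NCBITaxon:4577	Zea mays	maize|corn
NCBITaxon	NCBITaxon:9615	Canis lupus familiaris	dog
NCBITaxon	NCBITaxon:9796	Equus caballus	horse
PATO	PATO:0000384	male	
PATO	PATO:0000383	female	
PATO	PATO:0000586	increased size	enlarged|big
PATO	PATO:0000587	decreased size	reduced size|small
PATO	PATO:0000460	abnormal	aberrant
PATO	PATO:0000461	normal	wild type quality
PATO	PATO:0000322	red	
PATO	PATO:0001510	sterile	infertile
PATO	PATO:0000955	fertile	
UBERON	UBERON:0002107	liver	
UBERON	UBERON:0002048	lung	
UBERON	UBERON:0000955	brain	encephalon
UBERON	UBERON:0000948	heart	
UBERON	UBERON:0002113	kidney	
UBERON	UBERON:0000178	blood	whole blood
UBERON	UBERON:0002097	skin of body	skin
UBERON	UBERON:0002367	prostate gland	prostate
CL	CL:0000084	T cell	T lymphocyte|T-cell
CL	CL:0000236	B cell	B lymphocyte|B-cell
CL	CL:0000057	fibroblast	
CL	CL:0000182	hepatocyte	
CLO	CLO:0003684	HeLa cell	HeLa
CLO	CLO:0001230	HEK293 cell	HEK-293|293 cell
CLO	CLO:0009348	MCF-7 cell	MCF7
ENVO	ENVO:00001998	soil	
ENVO	ENVO:00002149	sea water	seawater|saline water
ENVO	ENVO:01000253	freshwater river biome	
ENVO	ENVO:00000873	freshwater biome	
ENVO	ENVO:01000174	forest biome	forest
ENVO	ENVO:00002261	forest soil	
ENVO	ENVO:00002007	sediment	
ENVO	ENVO:00002006	liquid water	water
EFO	EFO:0000635	organism part	
EFO	EFO:0000322	cell line	immortalized cell line
EFO	EFO:0000324	cell type	
EFO	EFO:0002012	whole organism	whole-organism
EFO	EFO:0005200	RNA	ribonucleic acid
EFO	EFO:0005201	DNA	deoxyribonucleic acid
EFO	EFO:0000787	tissue sample	
EFO	EFO:0009655	primary tumor	
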