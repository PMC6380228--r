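category	attribute_name
Biomedical characteristic	breed
Biomedical characteristic	ethnicity
Biomedical characteristic	host
Biomedical characteristic	sample_type
Biomedical characteristic	organism
Biomedical characteristic	Organism
Biomedical characteristic	tissue
Biomedical characteristic	species
Biomedical characteristic	strain
Biomedical characteristic	sex
Biomedical characteristic	Sex
Biomedical characteristic	body site
Biomedical characteristic	cell type
Biomedical characteristic	cell_type
Biomedical characteristic	genotype
Biomedical characteristic	disease state
Biomedical characteristic	disease
Biomedical characteristic	isolate
Biomedical characteristic	isolation_source
Biomedical characteristic	cultivar
Biomedical characteristic	serovar
Biomedical characteristic	Material
Biomedical characteristic	env_medium
Biomedical characteristic	env_broad_scale
Biomedical characteristic	env_local_scale
Biomedical characteristic	health_state
Biomedical characteristic	phenotype
Biomedical characteristic	smoker
Date	collection date
Date	collection_date
Date	collection timestamp
Date	time point
Date	birth_date
Date	receipt_date
Geographic location	geo_loc_name
Geographic location	geographic location
Geographic location	lat_lon
Geographic location	country
Geographic location	latitude and longitude
Measurement	depth
Measurement	elevation
Measurement	elev
Measurement	age
Measurement	altitude
Measurement	host_age
Measurement	temp
Measurement	ph
Measurement	salinity
Measurement	host taxonomy ID
Measurement	medication code
Identifier	sample id
Identifier	package
Identifier	model
Identifier	gap_accession
Identifier	gap_sample_id
Identifier	culture_collection
Identifier	specimen_voucher
Textual description	Sample_title
Textual description	project name
Textual description	Sample Name
Textual description	label
Textual description	title
Textual description	study name
Textual description	common name
Textual description	secondary description
Textual description	source name
Textual description	description
Textual description	treatment
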