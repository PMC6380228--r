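concept	attribute_name
Age	age
Age	age in years
Age	age (years)
Age	age_in_years
Age	age years
Age	age(years)
Age	age_years
Age	age (yr)
Age	age in days
Age	age_days
Age	AgeDays
Age	age (weeks)
Weight	total_mass
Weight	weight
Weight	weight kg
Weight	Weight..kg.
Weight	weight (kg)
Weight	weight_kg
Weight	Weight_lb
Weight	weight lbs
Weight	weight_g
Weight	Weight (g)
Geographic location	lat_lon
Geographic location	latitude and longitude
Geographic location	Lat-Long
Geographic location	geo_loc
Geographic location	lat_long
Geographic location	latitude_longitude
Geographic location	geographic location (latitude and longitude)
Geographic location	geographic_location
Height	height or length
Height	height
Height	Height
Height	height cm
Height	height (cm)
Height	height_cm
Height	Height (m)
Height	height_m
Height	height_meters
Elevation	elevation
Elevation	elev
Elevation	elevation(m)
Elevation	Elevation m
Elevation	elevation meters
Elevation	geographic location (elevation)
Birth date	birth_date
Birth date	date of birth
Birth date	Date of birth
Birth date	date_of_birth
Birth date	year of birth
Birth date	year_of_birth
Birth date	birth_year
Time point	time point
Time point	Timepoint
Time point	Time.point
Time point	time points
Time point	time-point
Time point	time_point
Time point	timepoint
Time point	time
Collection date/time	collection_date
Collection date/time	collection date
Collection date/time	collectiontime
Collection date/time	collected date
Collection date/time	collection day
Collection date/time	collection time
Collection date/time	collection timestamp
Country or Region	geographic location
Country or Region	country
Country or Region	country region
Country or Region	CountryOrRegion
Country or Region	country of origin
Country or Region	geographic location (country and/or sea)
Ethnicity	ethnicity
Ethnicity	ethinicity
Ethnicity	ethinity
Ethnicity	raceethnicity
Sample type	sample_type
Sample type	sample type
Sample type	sample-type
Sample type	type of sample
Sample type	type_sample
Sample type	type_of_sample
Sample type	sample type description
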