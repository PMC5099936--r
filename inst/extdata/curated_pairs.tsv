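gene	disease	disease_class	tissue	mas	fpkm	protein_detected
ACPP	Prostatic Neoplasms	disease of cellular proliferation	prostate	71.1	1916.41	Y
AGTR1	Diabetic Nephropathies	urinary system disease	kidney	84.66	11.97	N
CD22	Lymphoma, B-Cell	disease of cellular proliferation	lymph node	30.58	267.91	Y
CHRM1	Sjogren's Syndrome	immune system disease	salivary gland	79.04	18.19	N
DMD	Muscular Dystrophy, Duchenne	nervous system disease	skeletal muscle	74.91	41.85	Y
GLA	Fabry Disease	disease of metabolism	kidney	28.81	14.6	Y
HCAR2	Brain Ischemia	cardiovascular system disease	brain	85.26	0.12	Y
MC2R	Addison Disease	endocrine system disease	adrenal gland	59.95	36.71	N
PPIA	Arthritis, Rheumatoid	musculoskeletal system disease	lymph node	10.27	308.36	Y
PRKCD	Keratosis, Actinic	disease of cellular proliferation	skin	100	20.55	N
SCN9A	Neuralgia	nervous system disease	brain	33.83	0.68	Y
SLC12A3	Hypertension	cardiovascular system disease	kidney	33.3	142.87	Y
TUBB	Pancreatic Neoplasms	disease of cellular proliferation	pancreas	49.23	55.13	Y
VDR	Keratosis	integumentary system disease	skin	81.82	15.85	N
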