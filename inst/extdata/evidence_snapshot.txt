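#%mtlhon-evidence-snapshot schema=1
# Curated evidence fixture for the 54-variant Argentinean LHON cohort.
# Frequencies are PERCENT values.  Fields not printed in the study
# (benign-variant frequencies; proband counts / functional strengths of
# the three primary mutations) are synthetic curation placeholders.

variant: m.3308T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3316G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3372T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3395A>G
mitomap_status: disease_causing
freq_GenBank:             0.49
genbank_frequency_table1:            0.049
apogee_score:             0.62
proband_count: 4
functional_strength: supporting
phenotype_specific_supported: true
same_residue_pathogenic: p.Tyr30His

variant: m.3397A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3438G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3447A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3460G>A
mitomap_status: disease_causing
freq_GenBank:             0.06
proband_count: 50
functional_strength: strong

variant: m.3480A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3483G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3504T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3535T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3547A>G
mitomap_status: benign
freq_GenBank:              2.5
haplogroup_tag: B2

variant: m.3548T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3552T>A
mitomap_status: benign
freq_GenBank:                2
haplogroup_tag: C

variant: m.3591G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3594C>T
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3666G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3693G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3746C>T
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3808A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3915G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3918G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3992C>T
mitomap_status: benign
freq_GenBank:              1.5

variant: m.3999T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.4024A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.4092G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.4104A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.4216T>C
mitomap_status: benign
freq_GenBank:               12
haplogroup_tag: JT

variant: m.4248T>C
mitomap_status: benign
freq_GenBank:              1.8
haplogroup_tag: AE

variant: m.4259C>T
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11251A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11253T>C
mitomap_status: disease_causing
freq_GenBank:            0.506
freq_Helix:            0.948
freq_gnomAD:            0.673
genbank_frequency_table1:            0.503
apogee_score:             0.53
proband_count: 10

variant: m.11299T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11377G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11467A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11611G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11719G>A
mitomap_status: benign
freq_GenBank:               70

variant: m.11776T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.11778G>A
mitomap_status: disease_causing
freq_GenBank: 0
proband_count: 100
functional_strength: strong

variant: m.14305G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14318T>C
mitomap_status: benign
freq_GenBank:                2
haplogroup_tag: C

variant: m.14359C>T
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14364G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14410G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14461T>C
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14484T>C
mitomap_status: disease_causing
freq_GenBank:            0.122
proband_count: 50
functional_strength: strong

variant: m.14527A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14560G>A
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14561A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14566A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14582A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14587A>G
mitomap_status: benign
freq_GenBank:              1.5

variant: m.14634T>C
mitomap_status: benign
freq_GenBank:              1.5

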