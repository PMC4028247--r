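# Printed summary counts from the curated vesicle-transport factor survey.
# section=family: curated factors per complex family (core set)
# section=species_source: curated factors per source species before
#   removing the overlap shared by both species
# section=overlap: factors curated in both source species
# section=three_species_coorthologs: distinct (co-)orthologues per species
#   in the three-species (yeast / A. thaliana / S. lycopersicum) analysis
# section=class1_three_species: class-I numerator and classified
#   denominator for groups with members from all three species
section	key	n
family	COP-II	8
family	COP-I	16
family	CCV	18
family	Retromer/ESCRT	20
family	RabGTPase	68
family	Tethering	45
family	SNARE	65
species_source	arabidopsis	212
species_source	yeast	45
overlap	both	17
three_species_coorthologs	yeast	129
three_species_coorthologs	arabidopsis	340
three_species_coorthologs	tomato	307
class1_three_species	class_I	416
class1_three_species	classified_total	527
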