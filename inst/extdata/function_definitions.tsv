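function_id	name	definition
nitrogen_fixation	Nitrogen fixation (nitrogenase)	K02588 K02586+K02591 K02585 K02587+K02592
photosystem_II	Photosystem II core	K02703 K02706 K02705 K02704 K02707 K02708
fe_mn_transporter	Fe-Mn transporter MntH	K03322
glucoamylase	Glucoamylase	K01178
chitinase	Chitinase	K01183
riboflavin_biosynthesis	Riboflavin biosynthesis	K01497 K14652 K00082 K00794 K00793
chemotaxis	Chemotaxis (che cluster)	K03406 K03407 K03408 K03410,K03413 K03412
type_I_secretion	Type I secretion system	K12340 K11003 K11004
sec_srp	Sec-SRP secretion pathway	K03070+K03076 K03106,K03110 K03075 K03210
cobalt_transporter	Cobalt-magnesium transporter CorA	K03284
urea_transporter	Urea transporter Urt	K11959+K11960+K11961 K11962,K11963
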