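# Compounds contributed by acid-hydrolysed casein (casamino acids).
# Tryptophan is destroyed by acid hydrolysis and glutamine deamidated,
# so both are absent here and must be supplemented separately.
compound_id	name
ala_e	L-alanine
arg_e	L-arginine
asn_e	L-asparagine
asp_e	L-aspartate
cys_e	L-cysteine
glu_e	L-glutamate
gly_e	glycine
his_e	L-histidine
ile_e	L-isoleucine
leu_e	L-leucine
lys_e	L-lysine
met_e	L-methionine
phe_e	L-phenylalanine
pro_e	L-proline
ser_e	L-serine
thr_e	L-threonine
tyr_e	L-tyrosine
val_e	L-valine
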