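indicator_id,species,kappa,percent_agreement
demeanour,goat,1.00,100
demeanour,sheep,1.00,100
har,goat,1.00,100
har,sheep,0.70,87.5
social_withdrawal,goat,0.35,62
social_withdrawal,sheep,1.00,100
stereotypic,goat,0.65,88
stereotypic,sheep,0.55,75
shade_shelter,goat,0.65,85
shade_shelter,sheep,0.70,88
equipment,goat,0.55,75
equipment,sheep,0.60,80
dirtiness,goat,0.70,88
dirtiness,sheep,0.75,88
panting,goat,0.40,65
panting,sheep,0.45,68
stocking_density,goat,1.00,100
stocking_density,sheep,0.90,95
drinking_area,goat,0.80,90
drinking_area,sheep,0.80,90
feeding_area,goat,0.65,85
feeding_area,sheep,0.70,85
rumen_fill,goat,1.00,100
rumen_fill,sheep,1.00,100
bcs,goat,0.55,70
bcs,sheep,0.60,75
skin_pinch,goat,0.45,68
skin_pinch,sheep,0.45,68
lesions,goat,1.00,100
lesions,sheep,1.00,100
itching,goat,1.00,100
itching,sheep,0.85,93
fecal_soiling,goat,0.65,80
fecal_soiling,sheep,0.65,80
fleece,goat,0.55,70
fleece,sheep,0.55,70
hoof,goat,0.75,88
hoof,sheep,1.00,100
lameness,goat,0.90,95
lameness,sheep,0.90,95
mastitis,goat,0.55,70
mastitis,sheep,0.55,70
mucosa,goat,1.00,100
mucosa,sheep,1.00,100
ocular,goat,1.00,100
ocular,sheep,1.00,100
respiratory,goat,0.45,68
respiratory,sheep,0.45,68
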