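id,name,domain,species,scale_max,symbol,index_weight
demeanour,Demeanour,behaviour_mental,sheep;goat,2,S_D,0.30
har,Human-Animal Relationship,behaviour_mental,sheep;goat,2,S_HAR,0.25
social_withdrawal,Social Withdrawal,behaviour_mental,sheep;goat,2,S_SW,0.25
stereotypic,Stereotypic Behaviour,behaviour_mental,sheep;goat,2,S_St,0.20
shade_shelter,Access to Shade/Shelter,environment,sheep;goat,2,S_Sh,0.25
equipment,Condition of Equipment,environment,sheep;goat,2,,
dirtiness,Dirtiness (Fecal Soiling),environment,sheep;goat,2,S_Dir,0.15
panting,Panting (Thermal Stress),environment,sheep;goat,2,S_P,0.40
stocking_density,Stocking Density,environment,sheep;goat,2,S_Sd,0.20
drinking_area,Cleanliness of Drinking Area,nutrition,sheep;goat,2,,
feeding_area,Cleanliness of Feeding Area,nutrition,sheep;goat,2,,
rumen_fill,Rumen Fill,nutrition,sheep;goat,2,S_Ru,0.40
bcs,Body Condition Score (BCS),nutrition,sheep;goat,2,S_BCS,0.35
skin_pinch,Skin Pinch Test (Hydration),nutrition,sheep;goat,2,S_Sk,0.25
lesions,Body and Head Lesions,health,sheep;goat,2,S_Le,0.25
itching,Excessive Itching,health,sheep;goat,2,,
fecal_soiling,Fecal Soiling,health,sheep;goat,2,,
fleece,Fleece Loss and Quality,health,sheep;goat,2,,
hoof,Hoof Overgrowth,health,sheep;goat,2,S_Ho,0.15
lameness,Lameness,health,sheep;goat,2,S_L,0.30
mastitis,Mastitis-Udder Lesions,health,sheep;goat,2,,
mucosa,Mucosa Colour,health,sheep;goat,2,S_Mu,0.15
ocular,Ocular Discharge,health,sheep;goat,2,S_Oc,0.15
respiratory,Respiratory Quality,health,sheep;goat,2,,
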