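study_id,plot_id,year,sown_richness,treatment,species_id,sown_proportion,biomass,alteration_type,n_added
exp1,p01,1,2,control,Festuca,0.5,60,nutrient,10
exp1,p01,1,2,control,Trifolium,0.5,120,nutrient,10
exp1,p01,2,2,control,Festuca,0.5,75,nutrient,10
exp1,p01,2,2,control,Trifolium,0.5,110,nutrient,10
exp1,p02,1,1,control,Festuca,1,100,nutrient,10
exp1,p02,2,1,control,Festuca,1,90,nutrient,10
exp1,p03,1,1,control,Trifolium,1,200,nutrient,10
exp1,p03,2,1,control,Trifolium,1,210,nutrient,10
exp1,p04,1,2,treated,Festuca,0.5,95,nutrient,10
exp1,p04,1,2,treated,Trifolium,0.5,160,nutrient,10
exp1,p04,2,2,treated,Festuca,0.5,105,nutrient,10
exp1,p04,2,2,treated,Trifolium,0.5,170,nutrient,10
exp1,p05,1,1,treated,Festuca,1,150,nutrient,10
exp1,p05,2,1,treated,Festuca,1,140,nutrient,10
exp1,p06,1,1,treated,Trifolium,1,260,nutrient,10
exp1,p06,2,1,treated,Trifolium,1,280,nutrient,10
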