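diagnosis,pp,os
lymphoma,neoplastic,hematopoietic
osteosarcoma,neoplastic,musculoskeletal
mammary carcinoma,neoplastic,urogenital
lung carcinoma,neoplastic,respiratory
hepatocellular carcinoma,neoplastic,hepatic
brain tumor,neoplastic,neurologic
skin mast cell tumor,neoplastic,dermatologic
colorectal carcinoma,neoplastic,gastrointestinal
hemangiosarcoma,neoplastic,cardiovascular
thyroid carcinoma,neoplastic,endocrine
ocular melanoma,neoplastic,ophthalmologic
myocardial infarction,vascular,cardiovascular
stroke,vascular,neurologic
aortic thromboembolism,vascular,cardiovascular
pulmonary embolism,vascular,respiratory
chronic kidney disease,degenerative,urogenital
degenerative myelopathy,degenerative,neurologic
osteoarthritis,degenerative,musculoskeletal
arthritis,degenerative,musculoskeletal
cataract,degenerative,ophthalmologic
valvular degeneration,degenerative,cardiovascular
diabetes mellitus,metabolic,endocrine
obesity,metabolic,endocrine
hypothyroidism,metabolic,endocrine
hepatic lipidosis,metabolic,hepatic
electrolyte derangement,metabolic,urogenital
pneumonia,infectious,respiratory
parvoviral enteritis,infectious,gastrointestinal
sepsis,infectious,hematopoietic
leptospirosis,infectious,urogenital
pyoderma,infectious,dermatologic
meningoencephalitis,inflammatory,neurologic
pancreatitis,inflammatory,gastrointestinal
immune-mediated hemolytic anemia,inflammatory,hematopoietic
chronic hepatitis,inflammatory,hepatic
dermatitis,inflammatory,dermatologic
congenital heart defect,congenital,cardiovascular
portosystemic shunt,congenital,hepatic
hydrocephalus,congenital,neurologic
renal dysplasia,congenital,urogenital
vehicular trauma,traumatic,musculoskeletal
head trauma,traumatic,neurologic
penetrating wound,traumatic,dermatologic
rodenticide toxicosis,toxic,hematopoietic
ethylene glycol toxicosis,toxic,urogenital
chocolate toxicosis,toxic,cardiovascular
mushroom toxicosis,toxic,hepatic
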