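id,name,n_treated,fixed_cost,variable_cost_per_person,qaly_per_person,evidence_category,provider
physiotherapy_core,Core physiotherapy,4200,0,110,0.25,benefit,community
physio_extended,Extended physiotherapy,1200,0,180,0.35,benefit,community
pain_management_programme,Pain management programme,350,60000,1200,1.5,benefit,hospital
combined_physical_psychological,Combined physical and psychological programme,250,0,900,1.2,benefit,hospital
exercise_group_classes,Group exercise classes,1500,20000,70,0.45,benefit,community
cbt_back_pain,CBT for back pain,400,0,350,0.8,benefit,community
epidural_radicular,Epidural injection for radicular pain,300,0,700,0.5,benefit,hospital
nerve_root_block,Nerve root block,200,0,650,0.45,benefit,hospital
decompression_surgery,Spinal decompression surgery,150,0,5000,1.5,benefit,hospital
disc_replacement,Disc replacement,40,0,7000,1.8,benefit,hospital
radiofrequency_denervation,Radiofrequency denervation,180,0,800,0.6,benefit,hospital
self_management_education,Self-management education,1400,10000,25,0.06,benefit,community
triage_assessment_service,Triage and assessment service,900,0,95,0.1,benefit,community
occupational_therapy,Occupational therapy,300,0,300,0.29,benefit,community
psychology_support,Psychology support,230,0,550,0.5,benefit,community
mdt_case_review,Multidisciplinary case review,400,22000,450,0.65,benefit,hospital
tens,TENS,150,0,60,0,no_evidence,community
acupuncture,Acupuncture,250,0,120,0,no_evidence,community
traction,Traction,75,0,80,0,no_evidence,hospital
ultrasound_therapy,Therapeutic ultrasound,100,0,70,0,no_evidence,community
orthotic_insoles,Orthotic insoles,150,0,90,0,no_evidence,community
spinal_brace,Spinal brace,100,0,150,0,no_evidence,hospital
inpatient_other,Other inpatient admissions,250,0,600,0,no_evidence,hospital
outpatient_other,Other outpatient activity,500,0,150,0,no_evidence,hospital
laser_therapy,Low-level laser therapy,150,0,90,0,no_evidence,community
xray_spine,Spinal X-ray,2000,0,40,0,no_benefit,hospital
therapeutic_injections,Therapeutic spinal injections,300,0,250,0,no_benefit,hospital
surgery_fusion,Spinal fusion surgery,50,0,4000,0,no_benefit,hospital
mri_outside_guidelines,MRI outside guidelines,1150,0,100,0,possible_harm,hospital
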