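ocm_id,patient_id,site,histology,figo_stage,germline_brca,lines_of_chemo,seeding_density_96well
OCM.33-2,33,ascites,HGSOC,3C,WT,2,2000
OCM.38,38,ascites,HGSOC,4,WT,0,1500
OCM.46-3,46,ascites,HGSOC,3C,WT,3,1000
OCM.46-6,46,ascites,HGSOC,3C,WT,4,1000
OCM.59-3,59,ascites,HGSOC,3C,BRCA2,2,4000
OCM.64-3,64,ascites,non-HGSOC,3C,WT,1,3000
OCM.66-1,66,ascites,HGSOC,4,WT,1,1500
OCM.72,72,ascites,HGSOC,3C,BRCA1,2,2000
OCM.74-1,74,ascites,non-HGSOC,4,WT,3,3500
OCM.74-3,74,ascites,non-HGSOC,4,WT,3,3500
OCM.79,79,ascites,HGSOC,3C,WT,2,2000
OCM.87,87,ascites,HGSOC,3C,WT,0,2500
OCM.109,109,ascites,HGSOC,4,WT,1,2000
OCM.152,152,ascites,non-HGSOC,3C,WT,2,2500
OCM.191,191,ascites,HGSOC,3C,WT,1,1500
OCM.195,195,ascites,HGSOC,3C,WT,0,2000
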