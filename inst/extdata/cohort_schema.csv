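"name","epoch","type","unit","description"
"id","id","id","","opaque patient identifier"
"age","clinical","continuous","years","age at diagnosis"
"sex","clinical","categorical","0=female,1=male","sex"
"distance_anal_verge","clinical","continuous","cm","distance of the tumor from the anal verge"
"cea","clinical","continuous","ng/mL","carcinoembryonic antigen"
"tumor_grade","clinical","categorical","1=well,2=moderate,3=poor","histologic tumor grade"
"clinical_t","clinical","categorical","cT 1-4","clinical T classification"
"clinical_n","clinical","categorical","cN 0-2","clinical N classification"
"pre_rbc","pre_cbc","continuous","10^6/uL","pre-CRT red blood cell count"
"pre_hb","pre_cbc","continuous","g/dL","pre-CRT hemoglobin"
"pre_hct","pre_cbc","continuous","%","pre-CRT hematocrit"
"pre_mcv","pre_cbc","continuous","fL","pre-CRT mean red cell volume"
"pre_mch","pre_cbc","continuous","pg","pre-CRT mean red cell hemoglobin"
"pre_mchc","pre_cbc","continuous","g/dL","pre-CRT mean red cell hemoglobin concentration"
"pre_rdw","pre_cbc","continuous","%","pre-CRT red cell distribution width"
"pre_plt","pre_cbc","continuous","10^3/uL","pre-CRT platelet count"
"pre_pct","pre_cbc","continuous","%","pre-CRT plateletcrit"
"pre_mpv","pre_cbc","continuous","fL","pre-CRT mean platelet volume"
"pre_pdw","pre_cbc","continuous","%","pre-CRT platelet distribution width"
"pre_wbc","pre_cbc","continuous","10^3/uL","pre-CRT white blood cell count"
"pre_neutrophil","pre_cbc","continuous","/uL","pre-CRT absolute neutrophil count"
"pre_lymphocyte","pre_cbc","continuous","/uL","pre-CRT absolute lymphocyte count"
"pre_monocyte","pre_cbc","continuous","/uL","pre-CRT absolute monocyte count"
"pre_eosinophil","pre_cbc","continuous","/uL","pre-CRT absolute eosinophil count"
"pre_basophil","pre_cbc","continuous","/uL","pre-CRT absolute basophil count"
"pre_calcium","pre_chem","continuous","mg/dL","pre-CRT serum calcium"
"pre_phosphorus","pre_chem","continuous","mg/dL","pre-CRT serum phosphorus"
"pre_glucose","pre_chem","continuous","mg/dL","pre-CRT serum glucose"
"pre_uric_acid","pre_chem","continuous","mg/dL","pre-CRT serum uric acid"
"pre_cholesterol","pre_chem","continuous","mg/dL","pre-CRT total cholesterol"
"pre_total_protein","pre_chem","continuous","g/dL","pre-CRT total protein"
"pre_albumin","pre_chem","continuous","g/dL","pre-CRT serum albumin"
"pre_total_bilirubin","pre_chem","continuous","mg/dL","pre-CRT total bilirubin"
"pre_ast","pre_chem","continuous","U/L","pre-CRT aspartate transaminase"
"pre_alt","pre_chem","continuous","U/L","pre-CRT alanine aminotransferase"
"pre_alp","pre_chem","continuous","U/L","pre-CRT alkaline phosphatase"
"pre_creatinine","pre_chem","continuous","mg/dL","pre-CRT serum creatinine"
"early_rbc","early_cbc","continuous","10^6/uL","early-CRT (1-2 weeks into CRT) red blood cell count"
"early_hb","early_cbc","continuous","g/dL","early-CRT (1-2 weeks into CRT) hemoglobin"
"early_hct","early_cbc","continuous","%","early-CRT (1-2 weeks into CRT) hematocrit"
"early_mcv","early_cbc","continuous","fL","early-CRT (1-2 weeks into CRT) mean red cell volume"
"early_mch","early_cbc","continuous","pg","early-CRT (1-2 weeks into CRT) mean red cell hemoglobin"
"early_mchc","early_cbc","continuous","g/dL","early-CRT (1-2 weeks into CRT) mean red cell hemoglobin concentration"
"early_rdw","early_cbc","continuous","%","early-CRT (1-2 weeks into CRT) red cell distribution width"
"early_plt","early_cbc","continuous","10^3/uL","early-CRT (1-2 weeks into CRT) platelet count"
"early_pct","early_cbc","continuous","%","early-CRT (1-2 weeks into CRT) plateletcrit"
"early_mpv","early_cbc","continuous","fL","early-CRT (1-2 weeks into CRT) mean platelet volume"
"early_pdw","early_cbc","continuous","%","early-CRT (1-2 weeks into CRT) platelet distribution width"
"early_wbc","early_cbc","continuous","10^3/uL","early-CRT (1-2 weeks into CRT) white blood cell count"
"early_neutrophil","early_cbc","continuous","/uL","early-CRT (1-2 weeks into CRT) absolute neutrophil count"
"early_lymphocyte","early_cbc","continuous","/uL","early-CRT (1-2 weeks into CRT) absolute lymphocyte count"
"early_monocyte","early_cbc","continuous","/uL","early-CRT (1-2 weeks into CRT) absolute monocyte count"
"early_eosinophil","early_cbc","continuous","/uL","early-CRT (1-2 weeks into CRT) absolute eosinophil count"
"early_basophil","early_cbc","continuous","/uL","early-CRT (1-2 weeks into CRT) absolute basophil count"
"trg","outcome","categorical","AJCC TRG 0-3","AJCC tumor regression grade (0 = complete response, 3 = poor)"
"ypt","outcome","categorical","ypT 0-4","pathologic T classification after CRT and surgery"
"ypn","outcome","categorical","ypN 0-2","pathologic N classification after CRT and surgery"
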