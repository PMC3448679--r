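cancer,synonyms,incidence_per_100k,survival_5yr_pct,median_age_dx
breast,breast cancer|breast carcinoma,125,90,61
prostate,prostate cancer|prostatic carcinoma,110,98,66
lung,lung cancer|bronchus cancer|lung carcinoma,57,18,70
colorectal,colon cancer|rectal cancer|bowel cancer|colorectal cancer,38,65,67
uterine,uterine cancer|endometrial cancer|cancer of the uterus,27,81,62
melanoma,melanoma|skin melanoma,22,92,63
bladder,bladder cancer,20,77,73
non-hodgkin lymphoma,non-hodgkin lymphoma|non hodgkins lymphoma|nhl lymphoma,19,71,67
kidney,kidney cancer|renal cancer|renal cell carcinoma,16,74,64
thyroid,thyroid cancer,14,98,51
leukemia,leukemia|leukaemia,14,60,66
pancreatic,pancreatic cancer|cancer of the pancreas,13,9,70
oral,oral cancer|mouth cancer|tongue cancer|throat cancer,11,65,63
ovarian,ovarian cancer|cancer of the ovary,11,47,63
liver,liver cancer|hepatocellular carcinoma,8,18,64
stomach,stomach cancer|gastric cancer,7,31,68
myeloma,myeloma|multiple myeloma,7,50,69
cervical,cervical cancer|cancer of the cervix,7,68,50
brain,brain cancer|brain tumor|glioblastoma,6,33,59
testicular,testicular cancer,5.5,95,33
esophageal,esophageal cancer|oesophageal cancer,4,19,68
sarcoma,sarcoma|soft tissue cancer,3.4,65,59
larynx,larynx cancer|laryngeal cancer,3,61,66
hodgkins disease,hodgkins lymphoma|hodgkin's disease,2.7,87,39
vulvar,vulvar cancer,2.5,71,68
small intestine,small intestine cancer|small bowel cancer,2.2,67,66
anal,anal cancer,1.8,66,62
salivary,salivary gland cancer,1.3,72,64
gallbladder,gallbladder cancer,1.2,19,72
mesothelioma,mesothelioma,1,10,72
bone,bone cancer|osteosarcoma,0.9,67,42
eye,eye cancer|ocular melanoma,0.8,80,61
penile,penile cancer,0.8,65,68
nasopharyngeal,nasopharyngeal cancer|nasopharynx cancer,0.7,61,55
vaginal,vaginal cancer,0.7,47,67
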