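risk,cause,kind,exposure,rr,tmrel
ambient_pm,copd,continuous,2.4,1.00,2.4
ambient_pm,copd,continuous,10,1.10,2.4
ambient_pm,copd,continuous,25,1.25,2.4
ambient_pm,copd,continuous,50,1.45,2.4
ambient_pm,copd,continuous,100,1.75,2.4
ambient_pm,copd,continuous,200,2.10,2.4
ambient_pm,copd,continuous,300,2.30,2.4
ambient_pm,lri,continuous,2.4,1.00,2.4
ambient_pm,lri,continuous,10,1.12,2.4
ambient_pm,lri,continuous,25,1.28,2.4
ambient_pm,lri,continuous,50,1.48,2.4
ambient_pm,lri,continuous,100,1.70,2.4
ambient_pm,lri,continuous,200,1.95,2.4
ambient_pm,lri,continuous,300,2.10,2.4
ambient_pm,lung_cancer,continuous,2.4,1.00,2.4
ambient_pm,lung_cancer,continuous,10,1.06,2.4
ambient_pm,lung_cancer,continuous,25,1.15,2.4
ambient_pm,lung_cancer,continuous,50,1.28,2.4
ambient_pm,lung_cancer,continuous,100,1.45,2.4
ambient_pm,lung_cancer,continuous,200,1.62,2.4
ambient_pm,lung_cancer,continuous,300,1.70,2.4
ambient_pm,ihd,continuous,2.4,1.00,2.4
ambient_pm,ihd,continuous,10,1.12,2.4
ambient_pm,ihd,continuous,25,1.25,2.4
ambient_pm,ihd,continuous,50,1.38,2.4
ambient_pm,ihd,continuous,100,1.52,2.4
ambient_pm,ihd,continuous,200,1.63,2.4
ambient_pm,ihd,continuous,300,1.68,2.4
ambient_pm,stroke,continuous,2.4,1.00,2.4
ambient_pm,stroke,continuous,10,1.10,2.4
ambient_pm,stroke,continuous,25,1.22,2.4
ambient_pm,stroke,continuous,50,1.35,2.4
ambient_pm,stroke,continuous,100,1.48,2.4
ambient_pm,stroke,continuous,200,1.58,2.4
ambient_pm,stroke,continuous,300,1.62,2.4
ambient_pm,diabetes,continuous,2.4,1.00,2.4
ambient_pm,diabetes,continuous,10,1.08,2.4
ambient_pm,diabetes,continuous,25,1.16,2.4
ambient_pm,diabetes,continuous,50,1.25,2.4
ambient_pm,diabetes,continuous,100,1.34,2.4
ambient_pm,diabetes,continuous,200,1.40,2.4
ambient_pm,diabetes,continuous,300,1.42,2.4
ambient_pm,neonatal,continuous,2.4,1.00,2.4
ambient_pm,neonatal,continuous,10,1.05,2.4
ambient_pm,neonatal,continuous,25,1.12,2.4
ambient_pm,neonatal,continuous,50,1.20,2.4
ambient_pm,neonatal,continuous,100,1.30,2.4
ambient_pm,neonatal,continuous,200,1.38,2.4
ambient_pm,neonatal,continuous,300,1.42,2.4
household,copd,categorical,NA,2.30,NA
household,lri,categorical,NA,2.00,NA
household,lung_cancer,categorical,NA,1.60,NA
household,ihd,categorical,NA,1.40,NA
household,stroke,categorical,NA,1.40,NA
household,diabetes,categorical,NA,1.20,NA
household,neonatal,categorical,NA,1.30,NA
household,cataract,categorical,NA,1.50,NA
ozone,copd,continuous,32.4,1.00,32.4
ozone,copd,continuous,45,1.05,32.4
ozone,copd,continuous,60,1.10,32.4
ozone,copd,continuous,80,1.16,32.4
ozone,copd,continuous,100,1.20,32.4
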