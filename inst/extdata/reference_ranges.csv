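parameter,compartment,group,kind,center,sd,q25,q75,unit,source_label
Bone volume/tissue volume,trabecular,structural,mean_sd,17.7,2.6,NA,NA,%,age range 1.5-6.9 years
Trabecular thickness,trabecular,structural,mean_sd,101,11,NA,NA,um,age range 1.5-6.9 years
Trabecular number,trabecular,structural,mean_sd,1.77,0.31,NA,NA,1/mm,age range 1.5-6.9 years
Cortical width,cortical,structural,mean_sd,0.70,0.28,NA,NA,mm,age range 1.5-6.9 years
Osteoid thickness,trabecular,osteoid,mean_sd,5.8,1.4,NA,NA,um,age range 1.5-6.9 years
Osteoid surface/bone surface,trabecular,osteoid,mean_sd,34.0,6.7,NA,NA,%,age range 1.5-6.9 years
Osteoid volume/bone volume,trabecular,osteoid,mean_sd,3.97,1.19,NA,NA,%,age range 1.5-6.9 years
Osteoblast surface/bone surface,trabecular,surface,mean_sd,8.5,4.1,NA,NA,%,age range 1.5-6.9 years
Eroded surface/bone surface,trabecular,surface,mean_sd,14.8,4.4,NA,NA,%,age range 1.5-6.9 years
Osteoclast surface/bone surface,trabecular,surface,mean_sd,1.11,0.75,NA,NA,%,age range 1.5-6.9 years
Adipocyte area/marrow area,marrow,adiposity,undefined,NA,NA,NA,NA,%,not defined
CaMean,cancellous,bmdd,mean_sd,22.48,0.73,NA,NA,wt% Ca,healthy children (n=50)
CaPeak,cancellous,bmdd,mean_sd,23.39,0.70,NA,NA,wt% Ca,healthy children (n=50)
CaWidth,cancellous,bmdd,median_iqr,3.64,NA,3.47,3.99,dwt% Ca,healthy children (n=50)
CaLow,cancellous,bmdd,median_iqr,5.57,NA,4.78,6.80,% bone area,healthy children (n=50)
CaHigh,cancellous,bmdd,median_iqr,1.52,NA,0.62,2.22,% bone area,healthy children (n=50)
CaMean,cortical,bmdd,mean_sd,21.86,1.15,NA,NA,wt% Ca,healthy children (n=50)
CaPeak,cortical,bmdd,mean_sd,22.67,1.21,NA,NA,wt% Ca,healthy children (n=50)
CaWidth,cortical,bmdd,median_iqr,4.07,NA,3.73,4.68,dwt% Ca,healthy children (n=50)
CaLow,cortical,bmdd,median_iqr,6.86,NA,5.06,11.48,% bone area,healthy children (n=50)
CaHigh,cortical,bmdd,median_iqr,1.01,NA,0.44,1.89,% bone area,healthy children (n=50)
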