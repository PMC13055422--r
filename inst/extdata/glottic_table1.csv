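study,factor,log_or,se
elicin_2019,aci,0.51,0.16
elicin_2019,t_substage,0.48,0.21
elicin_2019,rt_technique,-0.17,0.25
elicin_2019,rt_dose,0.45,0.16
elicin_2019,gender,1.25,0.59
elicin_2019,age,-0.04,0.18
gultekin_2012,aci,0.73,0.28
gultekin_2012,t_substage,0.64,0.3
gultekin_2012,subglottic,0.41,0.35
gultekin_2012,rt_technique,0.3,0.18
gultekin_2012,gender,-0.92,1.27
gultekin_2012,smoking,0.97,1.01
gultekin_2012,age,1.21,0.3
gultekin_2012,tumor_grading,-0.08,0.18
yamazaki_2006,aci,-0.2,0.66
yamazaki_2006,t_substage,0.57,0.73
yamazaki_2006,fraction_size,-1.17,0.41
yamazaki_2006,gender,-0.62,1.05
yamazaki_2006,hb_level,-0.21,0.45
yamazaki_2006,smoking,0.25,0.72
yamazaki_2006,age,-0.26,0.44
almamgani_2013,aci,0.1,0.2
almamgani_2013,rt_dose,-0.11,0.11
almamgani_2013,fraction_size,0.47,0.06
almamgani_2013,gender,0.18,0.56
almamgani_2013,hb_level,0.99,0.16
almamgani_2013,smoking,1.31,0.1
almamgani_2013,age,0,0.25
bignardi_2004,aci,-0.73,0.47
bignardi_2004,cord_mobility,-0.07,0.63
bignardi_2004,subglottic,0.48,0.75
bignardi_2004,rt_technique,0.34,0.48
bignardi_2004,rt_dose,0.04,0.08
bignardi_2004,ott,0.18,0.2
bignardi_2004,field_size,0.17,0.57
bignardi_2004,tumor_grading,0,0.02
chung_2018,aci,0.51,0.4
chung_2018,t_substage,0.72,0.47
chung_2018,gender,-0.06,0.74
chung_2018,age,0.37,0.39
chung_2018,tumor_grading,-0.13,0.45
matsumoto_2016,aci,-1.03,0.83
matsumoto_2016,t_substage,1,0.68
matsumoto_2016,fraction_size,1.26,0.58
matsumoto_2016,ott,1.03,0.69
matsumoto_2016,gender,-0.2,1.14
matsumoto_2016,age,0.92,0.63
raitiola_2000,aci,1.34,0.47
raitiola_2000,t_substage,1.48,0.46
raitiola_2000,cord_mobility,1,0.64
deridder_2023,aci,-0.36,0.72
deridder_2023,t_substage,2.08,0.82
deridder_2023,field_size,0.02,0.03
deridder_2023,gender,-0.01,1.07
deridder_2023,smoking,2.22,0.73
deridder_2023,age,-0.02,0.04
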