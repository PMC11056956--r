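"dam_id","group","month","pups_born","pups_weaned"
"ctl_1","control",1,13,13
"ctl_1","control",2,13,13
"ctl_1","control",3,13,13
"ctl_2","control",1,13,13
"ctl_2","control",2,13,13
"ctl_2","control",3,13,13
"ctl_3","control",1,13,13
"ctl_3","control",2,13,13
"ctl_3","control",3,13,13
"ctl_4","control",1,13,13
"ctl_4","control",2,13,13
"ctl_4","control",3,13,13
"ctl_5","control",1,13,13
"ctl_5","control",2,13,13
"ctl_5","control",3,13,13
"ctl_6","control",1,13,13
"ctl_6","control",2,12,12
"adm_1","adenomyosis",1,7,7
"adm_2","adenomyosis",2,6,6
"adm_2","adenomyosis",3,6,6
"adm_3","adenomyosis",NA,0,0
"adm_4","adenomyosis",NA,0,0
"adm_5","adenomyosis",NA,0,0
"adm_6","adenomyosis",NA,0,0
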