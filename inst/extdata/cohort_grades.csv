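"mouse_id","group","grade"
"adm_01","adenomyosis","0"
"adm_02","adenomyosis","I"
"adm_03","adenomyosis","I"
"adm_04","adenomyosis","II"
"adm_05","adenomyosis","II"
"adm_06","adenomyosis","II"
"adm_07","adenomyosis","III"
"adm_08","adenomyosis","III"
"adm_09","adenomyosis","III"
"adm_10","adenomyosis","III"
"adm_11","adenomyosis","III"
"adm_12","adenomyosis","III"
"adm_13","adenomyosis","III"
"adm_14","adenomyosis","III"
"adm_15","adenomyosis","III"
"adm_16","adenomyosis","III"
"adm_17","adenomyosis","III"
"adm_18","adenomyosis","III"
"adm_19","adenomyosis","III"
"adm_20","adenomyosis","III"
"adm_21","adenomyosis","III"
"adm_22","adenomyosis","III"
"adm_23","adenomyosis","III"
"adm_24","adenomyosis","III"
"adm_25","adenomyosis","III"
"adm_26","adenomyosis","III"
"adm_27","adenomyosis","III"
"adm_28","adenomyosis","III"
"adm_29","adenomyosis","III"
"adm_30","adenomyosis","III"
"adm_31","adenomyosis","III"
"adm_32","adenomyosis","III"
"adm_33","adenomyosis","III"
"adm_34","adenomyosis","III"
"adm_35","adenomyosis","III"
"adm_36","adenomyosis","III"
"adm_37","adenomyosis","III"
"adm_38","adenomyosis","III"
"adm_39","adenomyosis","III"
"adm_40","adenomyosis","III"
"adm_41","adenomyosis","III"
"adm_42","adenomyosis","III"
"adm_43","adenomyosis","III"
"adm_44","adenomyosis","III"
"adm_45","adenomyosis","III"
"adm_46","adenomyosis","III"
"adm_47","adenomyosis","III"
"adm_48","adenomyosis","III"
"adm_49","adenomyosis","III"
"adm_50","adenomyosis","III"
"adm_51","adenomyosis","III"
"adm_52","adenomyosis","III"
"adm_53","adenomyosis","III"
"adm_54","adenomyosis","III"
"adm_55","adenomyosis","III"
"adm_56","adenomyosis","III"
"adm_57","adenomyosis","III"
"adm_58","adenomyosis","III"
"adm_59","adenomyosis","III"
"adm_60","adenomyosis","III"
"adm_61","adenomyosis","III"
"adm_62","adenomyosis","III"
"adm_63","adenomyosis","III"
"adm_64","adenomyosis","III"
"adm_65","adenomyosis","III"
"adm_66","adenomyosis","III"
"adm_67","adenomyosis","III"
"adm_68","adenomyosis","III"
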