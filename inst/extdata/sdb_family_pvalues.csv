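family,task,metric,p
ahi_cress,ahi5,accuracy,0.705
ahi_cress,ahi5,sensitivity,<0.001
ahi_cress,ahi5,specificity,0.041
ahi_cress,ahi5,lr_pos,0.074
ahi_cress,ahi5,lr_neg,<0.001
ahi_cress,ahi5,kappa,0.182
ahi_cress,ahi15,accuracy,0.035
ahi_cress,ahi15,sensitivity,0.110
ahi_cress,ahi15,specificity,0.247
ahi_cress,ahi15,lr_pos,0.168
ahi_cress,ahi15,lr_neg,0.068
ahi_cress,ahi15,kappa,0.013
ahi_cress,ahi30,accuracy,0.147
ahi_cress,ahi30,sensitivity,0.013
ahi_cress,ahi30,specificity,0.296
ahi_cress,ahi30,lr_pos,0.394
ahi_cress,ahi30,lr_neg,0.028
ahi_cress,ahi30,kappa,0.067
ahi_cress,fourclass,accuracy,0.019
ahi_cress,fourclass,underestimated,0.022
ahi_cress,fourclass,overestimated,0.624
ahi_cress,fourclass,kappa,0.014
ahi_cress_autar,ahi5,accuracy,0.705
ahi_cress_autar,ahi5,sensitivity,<0.001
ahi_cress_autar,ahi5,specificity,0.199
ahi_cress_autar,ahi5,lr_pos,0.205
ahi_cress_autar,ahi5,lr_neg,<0.001
ahi_cress_autar,ahi5,kappa,0.299
ahi_cress_autar,ahi15,accuracy,0.006
ahi_cress_autar,ahi15,sensitivity,0.007
ahi_cress_autar,ahi15,specificity,0.422
ahi_cress_autar,ahi15,lr_pos,0.245
ahi_cress_autar,ahi15,lr_neg,0.010
ahi_cress_autar,ahi15,kappa,<0.001
ahi_cress_autar,ahi30,accuracy,0.022
ahi_cress_autar,ahi30,sensitivity,<0.001
ahi_cress_autar,ahi30,specificity,0.015
ahi_cress_autar,ahi30,lr_pos,0.035
ahi_cress_autar,ahi30,lr_neg,0.001
ahi_cress_autar,ahi30,kappa,0.003
ahi_cress_autar,fourclass,accuracy,<0.001
ahi_cress_autar,fourclass,underestimated,<0.001
ahi_cress_autar,fourclass,overestimated,0.596
ahi_cress_autar,fourclass,kappa,<0.001
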