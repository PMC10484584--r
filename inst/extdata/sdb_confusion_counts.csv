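index,predicted,true,count
rei,None,None,16
rei,None,Mild,0
rei,None,Moderate,0
rei,None,Severe,0
rei,Mild,None,10
rei,Mild,Mild,38
rei,Mild,Moderate,20
rei,Mild,Severe,0
rei,Moderate,None,4
rei,Moderate,Mild,7
rei,Moderate,Moderate,38
rei,Moderate,Severe,26
rei,Severe,None,0
rei,Severe,Mild,0
rei,Severe,Moderate,6
rei,Severe,Severe,80
ahi_cress,None,None,22
ahi_cress,None,Mild,4
ahi_cress,None,Moderate,0
ahi_cress,None,Severe,0
ahi_cress,Mild,None,8
ahi_cress,Mild,Mild,34
ahi_cress,Mild,Moderate,13
ahi_cress,Mild,Severe,0
ahi_cress,Moderate,None,0
ahi_cress,Moderate,Mild,7
ahi_cress,Moderate,Moderate,42
ahi_cress,Moderate,Severe,15
ahi_cress,Severe,None,0
ahi_cress,Severe,Mild,0
ahi_cress,Severe,Moderate,9
ahi_cress,Severe,Severe,91
ahi_cress_autar,None,None,20
ahi_cress_autar,None,Mild,2
ahi_cress_autar,None,Moderate,0
ahi_cress_autar,None,Severe,0
ahi_cress_autar,Mild,None,10
ahi_cress_autar,Mild,Mild,35
ahi_cress_autar,Mild,Moderate,9
ahi_cress_autar,Mild,Severe,0
ahi_cress_autar,Moderate,None,0
ahi_cress_autar,Moderate,Mild,7
ahi_cress_autar,Moderate,Moderate,43
ahi_cress_autar,Moderate,Severe,7
ahi_cress_autar,Severe,None,0
ahi_cress_autar,Severe,Mild,1
ahi_cress_autar,Severe,Moderate,12
ahi_cress_autar,Severe,Severe,99
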