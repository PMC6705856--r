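cohort,grade,hiz,n
patient,1,FALSE,12
patient,2,FALSE,55
patient,3,FALSE,25
patient,4,FALSE,11
patient,5,FALSE,1
patient,3,TRUE,8
patient,4,TRUE,11
patient,5,TRUE,1
control,1,FALSE,7
control,2,FALSE,36
control,3,FALSE,6
control,4,FALSE,5
control,5,FALSE,1
control,3,TRUE,0
control,4,TRUE,4
control,5,TRUE,0
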