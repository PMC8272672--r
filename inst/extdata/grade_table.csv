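modality,grade0,gradeI,gradeII,gradeIII
MRI,6,10,10,34
arthroscopy,2,11,13,34
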