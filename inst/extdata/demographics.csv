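subject_id,group,age,sex
sub01,meditator,45.2,1
sub02,control,43.1,0
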