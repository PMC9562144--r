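cross_id	gene	cross_type	notes
wtf25_het	wtf25	heterozygous	synthetic example modelled on a driver cross
wt_control	none	homozygous_wildtype	synthetic wild-type control
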