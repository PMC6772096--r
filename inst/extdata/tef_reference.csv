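compound,acute_ref,chronic_ref
IMI,152,2820
CTD,2000,7380
THX,2716,12660
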