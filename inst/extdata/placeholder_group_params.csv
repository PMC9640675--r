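group,nifh_copies_per_cell,cell_rate_fmol_h,active_hours
Trichodesmium,2,1.5,12
UCYN-A,1,0.1,12
UCYN-B,1,0.5,12
Richelia,2,1.0,12
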