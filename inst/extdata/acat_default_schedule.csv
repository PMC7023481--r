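compartment,volume_ml,pH,transit_time_h
stomach,48.92,1.3,0.25
duodenum,44.57,6,0.26
jejunum1,166.6,6.2,0.94
jejunum2,131,6.4,0.75
ileum1,102,6.6,0.58
ileum2,75.35,6.9,0.42
ileum3,53.57,7.4,0.29
caecum,50.49,6.4,4.48
asc_colon,53.55,6.8,13.44
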