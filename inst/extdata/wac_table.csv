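sample,group,dry_g,wet_g,wac_printed_pct
PDL-02-1,PDL-02,0.291,0.384,24.4
PDL-02-2,PDL-02,0.283,0.376,24.8
PDL-02-3,PDL-02,0.283,0.414,31.7
PDL-02-4,PDL-02,0.283,0.345,18.0
PDL-04-1,PDL-04,0.290,0.334,13.1
PDL-04-2,PDL-04,0.285,0.328,13.1
PDL-04-3,PDL-04,0.288,0.343,15.8
PDL-04-4,PDL-04,0.289,0.342,15.5
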