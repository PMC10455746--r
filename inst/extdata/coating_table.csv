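series,syringe,n_pieces,weight_before_g,weight_after_g,ce_printed_pct
#1,1,50,3.157,3.684,14.3
#1,2,50,3.285,3.716,11.6
#1,3,55,3.605,4.166,13.5
#1,4,54,3.533,3.761,6.1
#2,1,50,3.283,3.894,15.7
#2,2,50,3.269,3.972,17.7
#2,3,55,3.613,4.487,19.5
#3,1,56,3.662,4.236,13.6
#3,2,55,3.592,4.304,16.5
#3,3,56,3.644,4.262,14.5
#3,4,56,3.646,4.434,17.8
#3,5,56,3.657,4.378,16.5
#3,6,55,3.592,4.112,12.6
#3,7,55,3.579,4.271,16.2
#3,8,55,3.587,4.120,12.9
#3,9,53,3.466,4.003,13.4
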