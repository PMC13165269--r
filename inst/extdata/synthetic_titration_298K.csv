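# temperature_K: 298
# f0_au: 1000
# marker: none
quencher_conc_M,f_au
0.00010000000000000000,405.248992394327047
0.00020000000000000001,244.020126094355277
0.00030000000000000003,185.777452926696355
0.00040000000000000002,137.091285322577420
0.00050000000000000001,114.906511845673691
0.00060000000000000006, 99.644544083497493
0.00070000000000000010, 80.702839204429779
0.00080000000000000004, 74.440881297990060
0.00090000000000000008, 67.284614352258544
0.00100000000000000002, 60.854718879830841
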