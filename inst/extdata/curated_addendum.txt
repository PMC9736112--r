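SYCP1, SYCP2, SYCP3, SYCE1, SYCE2, HORMAD2, MAEL, MEIKIN, MEIOB, MEIOC,
SYC E1L, TEX11, MAJIN, FAM9C, FAM9B, FAM9A, REC114, TEX19, BRME1, TEX14,
MSH4, TEX15
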