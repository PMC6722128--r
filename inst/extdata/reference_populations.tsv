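name	alt_alleles	total_alleles
gnomAD_EastAsian	49	19476
gnomAD_SouthAsian	3	30210
gnomAD_overall	54	279362
ExAC_EastAsian	23	8626
ExAC_SouthAsian	2	16510
ExAC_overall	25	120728
CNGMD_HanChinese	4	5254
CNGMD_overall	11	7352
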