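species	accuracy	precision	sensitivity	specificity
Spinner dolphin	72.20	73.90	93.19	21.89
Striped dolphin	62.49	62.05	84.68	37.41
Indo-Pacific bottlenose dolphin	63.61	63.19	92.09	20.68
Pantropical spotted dolphin	56.78	52.14	93.42	21.73
Dugong	75.50	75.93	98.08	15.02
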