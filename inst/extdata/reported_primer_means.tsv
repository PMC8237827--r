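primer	metric	mean
UBC812	accuracy	66.20
UBC812	precision	64.00
UBC812	sensitivity	86.06
UBC812	specificity	36.67
UBC817	accuracy	68.44
UBC817	precision	69.20
UBC817	sensitivity	93.23
UBC817	specificity	18.22
UBC818	accuracy	54.68
UBC818	precision	53.20
UBC818	sensitivity	92.51
UBC818	specificity	11.62
UBC826	accuracy	66.22
UBC826	precision	67.20
UBC826	sensitivity	94.88
UBC826	specificity	12.62
UBC827	accuracy	61.96
UBC827	precision	60.66
UBC827	sensitivity	94.08
UBC827	specificity	15.04
UBC847	accuracy	76.06
UBC847	precision	75.22
UBC847	sensitivity	93.33
UBC847	specificity	40.19
UBC848	accuracy	68.52
UBC848	precision	67.86
UBC848	sensitivity	91.67
UBC848	specificity	25.66
UBC880	accuracy	66.84
UBC880	precision	66.18
UBC880	sensitivity	92.59
UBC880	specificity	26.73
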