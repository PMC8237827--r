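primer	metric	Spinner dolphin	Striped dolphin	Indo-Pacific bottlenose dolphin	Pantropical spotted dolphin	Dugong
UBC812	accuracy	48.40	63.30	67.90	71.40	80.00
UBC812	precision	52.00	65.00	63.00	61.00	79.00
UBC812	sensitivity	76.47	76.47	85.71	91.67	100.00
UBC812	specificity	14.29	46.15	50.00	56.25	16.67
UBC817	accuracy	87.10	63.30	66.70	57.10	68.00
UBC817	precision	89.00	61.00	69.00	56.00	71.00
UBC817	sensitivity	96.15	87.50	94.74	93.33	94.44
UBC817	specificity	40.00	35.71	0.00	15.38	0.00
UBC818	accuracy	64.50	46.70	48.20	50.00	64.00
UBC818	precision	67.00	42.00	48.00	46.00	63.00
UBC818	sensitivity	95.24	83.33	92.31	91.67	100.00
UBC818	specificity	0.00	22.22	7.14	18.75	10.00
UBC826	accuracy	67.70	66.70	66.70	50.00	80.00
UBC826	precision	70.00	68.00	71.00	48.00	79.00
UBC826	sensitivity	95.45	89.47	89.47	100.00	100.00
UBC826	specificity	0.00	27.27	12.50	6.67	16.67
UBC827	accuracy	74.20	50.00	66.70	42.90	76.00
UBC827	precision	73.00	46.00	67.00	42.30	75.00
UBC827	sensitivity	100.00	84.62	94.12	91.67	100.00
UBC827	specificity	11.11	23.53	20.00	6.25	14.29
UBC847	accuracy	80.70	73.30	70.40	67.90	88.00
UBC847	precision	81.50	73.00	66.70	63.60	91.30
UBC847	sensitivity	95.65	88.89	93.33	93.33	95.45
UBC847	specificity	37.50	50.00	41.67	38.46	33.33
UBC848	accuracy	71.00	73.30	59.30	63.00	76.00
UBC848	precision	74.10	78.90	60.00	48.00	78.30
UBC848	sensitivity	90.91	78.95	93.75	100.00	94.74
UBC848	specificity	22.22	63.64	9.09	16.67	16.67
UBC880	accuracy	84.00	63.30	63.00	51.90	72.00
UBC880	precision	84.60	62.50	60.80	52.20	70.80
UBC880	sensitivity	95.65	88.24	93.33	85.71	100.00
UBC880	specificity	50.00	30.77	25.00	15.38	12.50
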