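measure	group	cases	n_group	printed_pct
male	morning	110419	252240	43.8
male	evening	68526	150888	45.4
never_smoker	morning	141599	252240	56.1
never_smoker	evening	74301	150888	49.2
current_smoker	morning	18949	252240	7.5
current_smoker	evening	19460	150888	12.9
depressive_symptoms	morning	25759	252240	10.2
depressive_symptoms	evening	18834	150888	12.5
major_depression	morning	18232	252240	7.2
major_depression	evening	12876	150888	8.5
gad	morning	3813	252240	1.5
gad	evening	2424	150888	1.6
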