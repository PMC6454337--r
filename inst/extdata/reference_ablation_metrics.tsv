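# Reference benchmark: phrase-partial feature-ablation results on the
# validation patients of the original (private) annotated clinical
# corpus. Macro/micro P, R, F1 as published; the relative F1
# improvements quoted alongside the benchmark are derivable from the F1
# columns.
configuration	macro_precision	macro_recall	macro_f1	micro_precision	micro_recall	micro_f1
basic	0.828	0.450	0.583	0.930	0.597	0.727
basic+is_icd9_code	0.874	0.472	0.613	0.887	0.640	0.744
basic+is_medical_unit	0.828	0.402	0.541	0.959	0.538	0.689
basic+entity_attributes	0.823	0.398	0.537	0.948	0.528	0.678
basic+stem	0.856	0.572	0.686	0.864	0.678	0.760
basic+section	0.783	0.544	0.642	0.874	0.682	0.766
basic+icd9_annotation	0.888	0.462	0.608	0.928	0.598	0.727
basic+icd9_annotation_post	0.823	0.478	0.605	0.912	0.604	0.727
best_combination	0.862	0.567	0.684	0.880	0.681	0.768
icd9_rule_baseline	0.803	0.139	0.236	0.885	0.059	0.111
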