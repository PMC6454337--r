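# Reference benchmark: per-construct precision and recall of the
# best-performing CRF tagger on the held-out test patients of the
# original (private) annotated clinical corpus, at the four evaluation
# levels. Microaverage rows are the pooled-count values as published;
# macroaverages and all F1 values are derivable with summarize_pr().
construct	level	precision	recall
BC	exact	0.833	0.625
DE	exact	0.324	0.350
FL	exact	0.387	0.279
WL	exact	0.571	0.215
ML	exact	0.577	0.090
PU	exact	0.304	0.200
SS	exact	0.551	0.541
UC	exact	0.207	0.124
VI	exact	0.687	0.456
WD	exact	0.517	0.394
Microaverage	exact	0.493	0.351
BC	partial	1	0.750
DE	partial	0.703	0.759
FL	partial	0.942	0.651
WL	partial	0.714	0.272
ML	partial	0.577	0.090
PU	partial	0.957	0.629
SS	partial	0.707	0.706
UC	partial	0.690	0.433
VI	partial	1	0.664
WD	partial	0.842	0.689
Microaverage	partial	0.785	0.571
BC	note	1	0.714
DE	note	0.604	0.873
FL	note	0.926	0.719
WL	note	0.866	0.586
ML	note	0.680	0.288
PU	note	0.929	0.722
SS	note	0.923	0.845
UC	note	0.682	0.556
VI	note	1	0.765
WD	note	0.894	0.781
Microaverage	note	0.806	0.726
BC	patient	1	0.667
DE	patient	0.625	1
FL	patient	0.864	0.826
WL	patient	0.857	0.632
ML	patient	0.700	0.583
PU	patient	1	0.667
SS	patient	0.935	0.967
UC	patient	0.857	0.857
VI	patient	1	0.846
WD	patient	0.912	0.912
Microaverage	patient	0.868	0.834
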