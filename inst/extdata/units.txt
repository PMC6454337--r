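# Medical measurement unit lexicon (case-insensitive exact match).
kg
g
mg
mcg
lb
lbs
oz
ml
dl
l
cc
cm
mm
in
mmhg
bpm
kcal
meq
mmol
iu
units
f
c
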