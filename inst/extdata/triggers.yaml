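# Trigger lexicons for the forward-scope entity-attribute detector.
negation:
  - "no"
  - not
  - denies
  - denied
  - without
  - negative
  - never
  - "free of"
uncertainty:
  - possible
  - possibly
  - may
  - might
  - perhaps
  - questionable
  - r/o
  - suspect
  - suspected
  - unclear
  - likely
subject:
  - daughter
  - husband
  - wife
  - son
  - mother
  - father
  - sister
  - brother
  - family
  - caregiver
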