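# Full ICD9 code universe for the Is-ICD9-Code feature.
046.0
046.1
046.2
046.3
046.4
046.5
046.6
046.7
046.8
046.9
244.9
250.00
250.01
260.0
260.1
260.2
260.3
260.4
260.5
260.6
260.7
260.8
260.9
261.0
261.1
261.2
261.3
261.4
261.5
261.6
261.7
261.8
261.9
262.0
262.1
262.2
262.3
262.4
262.5
272.0
272.4
276.1
276.51
285.9
290.0
290.00
290.01
290.02
290.03
290.04
290.05
290.06
290.07
290.08
290.09
290.1
290.10
290.11
290.12
290.13
290.14
290.15
290.16
290.17
290.2
290.3
290.4
290.5
290.6
290.7
290.8
290.9
294.0
294.1
294.2
294.3
294.4
294.5
294.6
294.7
294.8
294.9
300.00
307.7
311.0
327.23
331.0
331.1
331.2
331.3
331.4
331.5
331.6
331.7
331.8
331.9
362.01
368.0
368.1
368.2
368.3
368.4
368.5
368.6
368.7
368.8
368.9
369.0
369.00
369.01
369.02
369.03
369.04
369.05
369.06
369.07
369.08
369.09
369.1
369.10
369.11
369.12
369.13
369.14
369.15
369.16
369.17
369.18
369.19
369.2
369.20
369.21
369.22
369.23
369.24
369.25
369.26
369.27
369.28
369.29
369.3
369.30
369.31
369.32
369.33
369.34
369.4
369.5
369.6
369.7
369.8
369.9
401.1
401.9
402.90
414.00
427.31
428.0
443.9
482.9
486.0
496.0
530.81
578.9
585.3
599.0
600.00
625.6
707.0
707.00
707.01
707.02
707.03
707.04
707.05
707.06
707.07
707.08
707.09
707.1
707.10
707.11
707.12
707.13
707.14
707.15
707.16
707.17
707.18
707.19
707.2
707.20
707.21
707.22
707.23
707.24
707.3
707.4
707.5
707.6
707.7
707.8
707.9
715.90
719.7
724.2
780.79
781.2
783.0
783.00
783.01
783.02
783.1
783.2
783.21
783.22
783.3
783.4
783.5
783.6
783.7
783.8
783.9
786.50
787.6
788.0
788.00
788.01
788.02
788.1
788.2
788.3
788.4
788.5
788.6
788.7
788.8
788.9
995.92
E880.0
E880.1
E880.2
E880.3
E880.4
E880.5
E880.6
E880.7
E880.8
E880.9
E881.0
E881.1
E881.2
E881.3
E881.4
E881.5
E881.6
E881.7
E881.8
E881.9
E882.0
E882.1
E882.2
E882.3
E882.4
E882.5
E882.6
E882.7
E882.8
E882.9
E883.0
E883.1
E883.2
E883.3
E883.4
E883.5
E883.6
E883.7
E883.8
E883.9
E884.0
E884.1
E884.2
E884.3
E884.4
V46.0
V46.00
V46.01
V46.02
V46.03
V46.04
V46.05
V46.06
V46.07
V46.08
V46.09
V46.1
V46.10
V46.11
V46.12
V46.13
V46.14
V46.15
V46.16
V46.17
V46.18
V46.2
V46.3
V46.4
V46.5
V46.6
V46.7
V46.8
V46.9
V60.0
V60.00
V60.01
V60.02
V60.03
V60.1
V60.2
V60.3
V60.4
V60.5
V60.6
V60.7
V60.8
V60.9
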