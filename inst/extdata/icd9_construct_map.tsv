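# ICD9 code -> construct map (editable).
# Assembled from the standard diagnostic code families for each
# geriatric syndrome; per-construct counts are pinned by tests,
# membership is configurable. Synthetic stand-in for the original
# curated 295-code list, which is not publicly deposited.
code	construct
787.6	BC
307.7	BC
290.0	DE
290.1	DE
290.2	DE
290.3	DE
290.4	DE
290.5	DE
290.6	DE
290.7	DE
290.8	DE
290.9	DE
294.0	DE
294.1	DE
294.2	DE
294.3	DE
294.4	DE
294.5	DE
294.6	DE
294.7	DE
294.8	DE
294.9	DE
331.0	DE
331.1	DE
331.2	DE
331.3	DE
331.4	DE
331.5	DE
331.6	DE
331.7	DE
331.8	DE
331.9	DE
046.0	DE
046.1	DE
046.2	DE
046.3	DE
046.4	DE
046.5	DE
046.6	DE
046.7	DE
046.8	DE
046.9	DE
290.00	DE
290.01	DE
290.02	DE
290.03	DE
290.04	DE
290.05	DE
290.06	DE
290.07	DE
290.08	DE
290.09	DE
290.10	DE
290.11	DE
290.12	DE
290.13	DE
290.14	DE
290.15	DE
290.16	DE
290.17	DE
E880.0	FL
E880.1	FL
E880.2	FL
E880.3	FL
E880.4	FL
E880.5	FL
E880.6	FL
E880.7	FL
E880.8	FL
E880.9	FL
E881.0	FL
E881.1	FL
E881.2	FL
E881.3	FL
E881.4	FL
E881.5	FL
E881.6	FL
E881.7	FL
E881.8	FL
E881.9	FL
E882.0	FL
E882.1	FL
E882.2	FL
E882.3	FL
E882.4	FL
E882.5	FL
E882.6	FL
E882.7	FL
E882.8	FL
E882.9	FL
E883.0	FL
E883.1	FL
E883.2	FL
E883.3	FL
E883.4	FL
E883.5	FL
E883.6	FL
E883.7	FL
E883.8	FL
E883.9	FL
E884.0	FL
E884.1	FL
E884.2	FL
E884.3	FL
E884.4	FL
783.21	WL
783.22	WL
783.0	WL
783.1	WL
783.2	WL
783.3	WL
783.4	WL
783.5	WL
783.6	WL
783.7	WL
783.8	WL
783.9	WL
783.00	WL
783.01	WL
783.02	WL
260.0	ML
260.1	ML
260.2	ML
260.3	ML
260.4	ML
260.5	ML
260.6	ML
260.7	ML
260.8	ML
260.9	ML
261.0	ML
261.1	ML
261.2	ML
261.3	ML
261.4	ML
261.5	ML
261.6	ML
261.7	ML
261.8	ML
261.9	ML
262.0	ML
262.1	ML
262.2	ML
262.3	ML
262.4	ML
262.5	ML
707.0	PU
707.1	PU
707.2	PU
707.3	PU
707.4	PU
707.5	PU
707.6	PU
707.7	PU
707.8	PU
707.9	PU
707.00	PU
707.01	PU
707.02	PU
707.03	PU
707.04	PU
707.05	PU
707.06	PU
707.07	PU
707.08	PU
707.09	PU
707.10	PU
707.11	PU
707.12	PU
707.13	PU
707.14	PU
707.15	PU
707.16	PU
707.17	PU
707.18	PU
707.19	PU
707.20	PU
707.21	PU
707.22	PU
707.23	PU
707.24	PU
V60.0	SS
V60.1	SS
V60.2	SS
V60.3	SS
V60.4	SS
V60.5	SS
V60.6	SS
V60.7	SS
V60.8	SS
V60.9	SS
V60.00	SS
V60.01	SS
V60.02	SS
V60.03	SS
625.6	UC
788.0	UC
788.1	UC
788.2	UC
788.3	UC
788.4	UC
788.5	UC
788.6	UC
788.7	UC
788.8	UC
788.9	UC
788.00	UC
788.01	UC
788.02	UC
369.0	VI
369.1	VI
369.2	VI
369.3	VI
369.4	VI
369.5	VI
369.6	VI
369.7	VI
369.8	VI
369.9	VI
368.0	VI
368.1	VI
368.2	VI
368.3	VI
368.4	VI
368.5	VI
368.6	VI
368.7	VI
368.8	VI
368.9	VI
369.00	VI
369.01	VI
369.02	VI
369.03	VI
369.04	VI
369.05	VI
369.06	VI
369.07	VI
369.08	VI
369.09	VI
369.10	VI
369.11	VI
369.12	VI
369.13	VI
369.14	VI
369.15	VI
369.16	VI
369.17	VI
369.18	VI
369.19	VI
369.20	VI
369.21	VI
369.22	VI
369.23	VI
369.24	VI
369.25	VI
369.26	VI
369.27	VI
369.28	VI
369.29	VI
369.30	VI
369.31	VI
369.32	VI
369.33	VI
369.34	VI
719.7	WD
781.2	WD
V46.0	WD
V46.1	WD
V46.2	WD
V46.3	WD
V46.4	WD
V46.5	WD
V46.6	WD
V46.7	WD
V46.8	WD
V46.9	WD
V46.00	WD
V46.01	WD
V46.02	WD
V46.03	WD
V46.04	WD
V46.05	WD
V46.06	WD
V46.07	WD
V46.08	WD
V46.09	WD
V46.10	WD
V46.11	WD
V46.12	WD
V46.13	WD
V46.14	WD
V46.15	WD
V46.16	WD
V46.17	WD
V46.18	WD
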