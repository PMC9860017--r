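cohort	n_cases	n_controls	or	ci_low	ci_high
discovery	2794	2010	16.8	0.90	312.2
replication	6596	2584	2.83	1.20	6.64
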