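stage	n_cases	n_controls
discovery	12577	23475
replication	10035	16139
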