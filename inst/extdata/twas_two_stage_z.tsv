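gene	z_discovery	z_replication	z_combined_published
C9ORF72	8.8166	4.7791	10.01
SCFD1	5.151355	3.46811	6.20
SLC9A8	3.5221	4.4035	5.31
NUP50	-4.76	-2.3339	-5.27
NDUFC2	-4.5597	-2.194	-5.03
JAKMIP3	4.05207	2.6297	4.82
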