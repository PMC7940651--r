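name	H2	E_P	E_F	E_S	E_U	E_total	G_SNP	G_CNV	G_A_reported	residual_hybrid_printed
ASD	0.924	0	NA	NA	NA	NA	0.17	0.2	0.924	0
ADHD	0.763	0.2	NA	NA	NA	NA	0.28	0.02	0.468	0.195
bipolar disorder	0.676	0.27	NA	NA	NA	NA	0.25	NA	0.333	0.208
depression	0.579	0.362	NA	NA	NA	NA	0.21	NA	0.192	0.207
schizophrenia	0.562	0.254	NA	NA	NA	NA	0.23	0.04	0.308	0.127
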