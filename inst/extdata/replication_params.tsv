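# Mean replication-fork rate (kb/min) and S-phase duration (min) per organism.
organism	fork_rate_kb_min	s_phase_min
tcruzi	2.05	591.6
lmajor	2.44	192.0
tbrucei	3.06	138.6
scerevisiae	1.60	30.0
spombe	0.91	24.0
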