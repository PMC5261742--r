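chrA	0	60	0fold
chrA	60	120	4fold
chrA	120	180	CNS
chrA	180	240	CCS
chrA	240	300	other
chrB	0	400	other
chrC	0	250	0fold
chrC	250	500	other
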