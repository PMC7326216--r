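sample_id	target_content	molarity
PLI-5	0.012	1.8
PLI-8	0.085	2.4
PLI-15	0.031	1.1
PLI-20	0.057	2.0
PLI-28	0.140	2.9
PLI-33	0.019	0.9
PLI-39	0.102	2.2
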