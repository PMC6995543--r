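file	chain	start	end	domain_id
synthetic_chain.pdb	A	1	30	syn_dom1
synthetic_chain.pdb	A	31	60	syn_dom2
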