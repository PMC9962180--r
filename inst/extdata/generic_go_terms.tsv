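term_id	term_name
GO:0035278	miRNA mediated inhibition of translation
GO:0035195	gene silencing by miRNA
GO:0031047	gene silencing by RNA
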