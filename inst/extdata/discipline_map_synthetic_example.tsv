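journal	discipline
Synthetic Journal A	Orthogeriatrics
Synthetic Journal B	Traumatology
Synthetic Journal C	Internal Medicine
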