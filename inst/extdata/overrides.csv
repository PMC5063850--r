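compound_id,forced_final,rationale
161,TP,mammary-gland signal shared across the alpha1-antagonist class supports a positive final call
184,TN,unspecific tumor pattern unrelated to the subchronic adrenal finding; judged negative overall
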