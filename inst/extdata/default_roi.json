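{"corners":[[104,55],[250,50],[256,188],[98,193]],"reference_frame":1}
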