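{"error":"tips3d_bad_input","message":"usage: tips3d <phantom|measure|cohort|simulate> [--flags]"}
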