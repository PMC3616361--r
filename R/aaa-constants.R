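# state labels in canonical order; used everywhere an unnamed vector is indexed
STATES <- c("M", "N", "A", "D", "S", "E")
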