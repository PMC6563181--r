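# Measurement vocabulary shared across modules.

MEASURES <- c("M", "MW", "B", "CSW1", "CSW2")
MANUBRIUM_MEASURES <- c("M", "MW")
CORPUS_MEASURES <- c("B", "CSW1", "CSW2")
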