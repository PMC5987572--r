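# shared constants: base alphabet and the fixed feature ordering

DNA_BASES <- c("A", "C", "G", "T")

# 12 motif feature bins: strand (given sequence "plus" / reverse complement
# "minus") x disjoint TSS-distance annuli, proximal to distal
MOTIF_BIN_NAMES <- as.vector(outer(
  c("up10k", "up2k", "up500", "down500", "down2k", "down10k"),
  c("plus", "minus"),
  function(b, s) paste(s, b, sep = "_")))
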