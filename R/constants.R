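BASES <- c("A", "C", "G", "T")

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0)),
  c("TAA", "TAG", "TGA")
)

KR_CODONS <- c("AAA", "AAG", "CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
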