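# random DNA of length n at a given GC content (independent positions)
random_dna <- function(n, gc = 0.45) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# region of a transcript position under the 0-based half-open model intervals
position_region <- function(pos, model) {
  dplyr::case_when(
    pos < model$cds_start ~ "utr5",
    pos < model$cds_end ~ "cds",
    pos < model$length ~ "utr3",
    TRUE ~ NA_character_
  )
}

assert_models <- function(models) {
  need <- c("gene_id", "transcript_id", "sequence", "cds_start", "cds_end",
            "length", "compartment")
  miss <- setdiff(need, names(models))
  if (length(miss) > 0) {
    abort(paste0("`models` is missing columns: ", paste(miss, collapse = ", ")))
  }
  invisible(models)
}

assert_reads <- function(reads) {
  need <- c("sample_id", "assay", "condition", "transcript_id", "pos", "length")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    abort(paste0("`reads` is missing columns: ", paste(miss, collapse = ", ")))
  }
  invisible(reads)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate a DNA string (standard code) up to but excluding the first stop;
# returns list(peptide, hit_stop)
translate_to_stop <- function(dna) {
  n_cod <- nchar(dna) %/% 3
  if (n_cod == 0) return(list(peptide = "", hit_stop = FALSE))
  codons <- substring(dna, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(paste(codons, collapse = "")),
    if.fuzzy.codon = "X"
  ))
  aa <- strsplit(aa, "")[[1]]
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) {
    list(peptide = paste(aa, collapse = ""), hit_stop = FALSE)
  } else {
    list(peptide = paste(head(aa, stop_at[1] - 1), collapse = ""), hit_stop = TRUE)
  }
}
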