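suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
})

# compact simulation shared by several test files (built once per file load)
tiny_config <- function(seed = 11, n_genes = 60,
                        n_per_class = c(both_up = 5L, both_down = 5L,
                                        mrna_only_up = 5L,
                                        mrna_only_down = 5L,
                                        rpf_only_up = 10L,
                                        rpf_only_down = 5L,
                                        null = NA_integer_),
                        n_quadruplex_genes = c(utr5 = 8L, cds = 0L,
                                               utr3 = 8L),
                        depth = 300, ...) {
  sim_config(seed = seed, n_genes = n_genes, n_per_class = n_per_class,
             n_quadruplex_genes = n_quadruplex_genes, depth = depth, ...)
}

# counts tibble straight from a genes x samples matrix (2 x 2 design)
counts_from_matrix <- function(m, condition = c("control", "control",
                                                "heat", "heat"),
                               assay = "rna", region_len = 1000L) {
  rep_id <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  tibble::tibble(
    gene_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    assay = assay,
    condition = rep(condition, each = nrow(m)),
    replicate = rep(rep_id, each = nrow(m)),
    region = "cds",
    count = as.vector(m),
    region_len = region_len,
    total = rep(pmax(colSums(m), 1L), each = nrow(m))
  )
}

# minimal transcript-model tibble for hand-built fixtures
toy_model <- function(gene_id = "g1", utr5 = 30L, cds = 90L, utr3 = 30L,
                      sequence = NULL) {
  L <- utr5 + cds + utr3
  sequence <- sequence %||%
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  stopifnot(nchar(sequence) == L)
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
    sequence = sequence,
    utr5_start = 0L, utr5_end = utr5, cds_start = utr5,
    cds_end = utr5 + cds, utr3_start = utr5 + cds, utr3_end = L,
    length = L, compartment = "nuclear", operon_id = NA_character_
  )
}

toy_reads <- function(transcript_id, pos, length,
                      sample_id = "rna_control_1", assay = "rna",
                      condition = "control", replicate = 1L) {
  tibble::tibble(sample_id = sample_id, assay = assay, condition = condition,
                 replicate = replicate, transcript_id = transcript_id,
                 pos = as.integer(pos), length = as.integer(length))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
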