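#' Protein production from ribosome-footprint density
#'
#' Production per gene is the RPF density over the CDS: `rpf_rpkm` mode uses
#' RPF rpkm directly (each footprint is taken to produce one protein, an
#' upper bound ignoring drop-off and degradation); `te` mode divides by the
#' mRNA rpkm (pseudocount 0.5 rpkm). For plastid genes the mRNA level of a
#' polycistronic operon is shared: it is computed from the summed mRNA
#' counts and CDS lengths of the operon's ORFs. Both columns are always
#' emitted; `mode` selects which one `production` points at. Replicates are
#' averaged within condition.
#'
#' @param counts Output of [count_reads()] (CDS region, both assays).
#' @param models Transcript model tibble (plastid genes flagged via
#'   `compartment`, operons via `operon_id`).
#' @param mode `"rpf_rpkm"` (headline default) or `"te"`.
#' @return Tibble: `gene_id`, `condition`, `rpf_rpkm`, `mrna_rpkm`, `te`,
#'   `production`, `unstable` (TRUE when te was computed against zero mRNA).
#' @export
protein_production <- function(counts, models, mode = c("rpf_rpkm", "te")) {
  mode <- match.arg(mode)
  rpkm <- normalize_counts(counts, "rpkm") %>%
    group_by(.data$gene_id, .data$assay, .data$condition) %>%
    summarise(rpkm = mean(.data$rpkm), count = sum(.data$count),
              region_len = .data$region_len[1],
              total = mean(.data$total), .groups = "drop")
  wide <- rpkm %>%
    select("gene_id", "assay", "condition", "rpkm") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "rpkm") %>%
    rename(rpf_rpkm = "rpf", mrna_rpkm = "rna")

  # operon-shared mRNA: pooled counts / pooled length within the operon
  ops <- models %>% filter(!is.na(.data$operon_id)) %>%
    select("gene_id", "operon_id")
  if (nrow(ops) > 0) {
    op_rpkm <- rpkm %>%
      filter(.data$assay == "rna") %>%
      inner_join(ops, by = "gene_id") %>%
      group_by(.data$operon_id, .data$condition) %>%
      summarise(op_mrna_rpkm = sum(.data$count) * 1e9 /
                  (sum(.data$region_len) * mean(.data$total)),
                .groups = "drop")
    wide <- wide %>%
      left_join(ops, by = "gene_id") %>%
      left_join(op_rpkm, by = c("operon_id", "condition")) %>%
      mutate(mrna_rpkm = dplyr::coalesce(.data$op_mrna_rpkm, .data$mrna_rpkm)) %>%
      select(-"operon_id", -"op_mrna_rpkm")
  }
  wide %>%
    mutate(te = .data$rpf_rpkm / (.data$mrna_rpkm + 0.5),
           unstable = .data$mrna_rpkm == 0,
           production = if (mode == "rpf_rpkm") .data$rpf_rpkm else .data$te)
}

#' Audit complex stoichiometry against ribosome densities
#'
#' Normalizes observed production within each complex and condition to its
#' lowest-stoichiometry subunit, compares with the expected integer ratios,
#' reports Spearman's rho between production and stoichiometry, and flags
#' complexes whose subunit heat/control fold changes spread by more than
#' `disprop_fold` as disproportionately regulated.
#'
#' @param production Output of [protein_production()].
#' @param complexes Tibble: `complex`, `gene_id`, `stoichiometry`,
#'   `operon_id`.
#' @param disprop_fold Max/min subunit fold-change ratio above which a
#'   complex is flagged.
#' @return Object of class `riboheat_stoich`: `subunits` (per subunit per
#'   condition: production, obs_ratio, exp_ratio, fold_change), `complexes`
#'   (per complex per condition: spearman rho, n; plus disproportionate
#'   flag), `skipped`.
#' @export
stoichiometry_audit <- function(production, complexes, disprop_fold = 2) {
  sub <- complexes %>%
    inner_join(production, by = "gene_id")
  skipped <- sub %>%
    group_by(.data$complex, .data$condition) %>%
    summarise(n_q = sum(.data$production > 0), .groups = "drop") %>%
    filter(.data$n_q < 2) %>%
    mutate(reason = "fewer than 2 quantified subunits")
  sub <- sub %>% anti_join(skipped, by = c("complex", "condition"))
  if (nrow(sub) > 0) {
    sub <- sub %>%
      group_by(.data$complex, .data$condition) %>%
      mutate(ref = .data$production[which.min(.data$stoichiometry)][1],
             obs_ratio = .data$production / .data$ref,
             exp_ratio = .data$stoichiometry /
               min(.data$stoichiometry)) %>%
      ungroup() %>%
      select(-"ref")
  } else {
    sub <- sub %>% mutate(obs_ratio = double(), exp_ratio = double())
  }

  cx <- sub %>%
    group_by(.data$complex, .data$condition) %>%
    summarise(spearman = suppressWarnings(
      cor(.data$production, .data$stoichiometry, method = "spearman")),
      n = dplyr::n(), .groups = "drop")

  fc <- sub %>%
    select("complex", "gene_id", "condition", "production") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "production")
  if (all(c("control", "heat") %in% names(fc))) {
    fc <- fc %>%
      mutate(fold_change = (.data$heat + 1e-12) / (.data$control + 1e-12))
    disp <- fc %>%
      group_by(.data$complex) %>%
      summarise(fc_spread = max(.data$fold_change) / min(.data$fold_change),
                .groups = "drop") %>%
      mutate(disproportionate = .data$fc_spread > disprop_fold)
    sub <- sub %>% left_join(fc %>% select("complex", "gene_id", "fold_change"),
                             by = c("complex", "gene_id"))
    cx <- cx %>% left_join(disp, by = "complex")
  }
  structure(list(subunits = sub, complexes = cx, skipped = skipped,
                 disprop_fold = disprop_fold),
            class = "riboheat_stoich")
}

#' @export
print.riboheat_stoich <- function(x, ...) {
  cat("riboheat stoichiometry audit\n")
  print(x$complexes)
  invisible(x)
}

#' @rdname stoichiometry_audit
#' @param x A `riboheat_stoich`.
#' @param ... Unused.
#' @export
tidy.riboheat_stoich <- function(x, ...) x$subunits

#' @rdname stoichiometry_audit
#' @export
glance.riboheat_stoich <- function(x, ...) {
  tibble(n_complexes = dplyr::n_distinct(x$complexes$complex),
         n_skipped = nrow(x$skipped),
         n_disproportionate = if ("disproportionate" %in% names(x$complexes))
           sum(x$complexes$disproportionate[!duplicated(x$complexes$complex)])
         else NA_integer_)
}

#' Correlate protein production with an external abundance table
#'
#' Spearman correlation over the gene intersection; fewer than 5 shared
#' genes triggers a low-n warning flag.
#'
#' @param production Output of [protein_production()] for one condition.
#' @param abundance Tibble: `gene_id`, `abundance`.
#' @return A list: `rho`, `n`, `low_n`, `pairs` (the joined table).
#' @export
abundance_correlation <- function(production, abundance) {
  pairs <- production %>%
    inner_join(abundance, by = "gene_id") %>%
    select("gene_id", "production", "abundance")
  low_n <- nrow(pairs) < 5
  if (low_n) warn("fewer than 5 genes shared with the abundance table")
  rho <- if (nrow(pairs) >= 2) {
    suppressWarnings(cor(pairs$production, pairs$abundance,
                         method = "spearman"))
  } else NA_real_
  list(rho = rho, n = nrow(pairs), low_n = low_n, pairs = pairs)
}
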