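#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (nonzero in every sample) of the
#' ratio of its count to the gene's geometric mean across samples; factors
#' are rescaled to have geometric mean 1.
#'
#' @param counts Output of [count_reads()] for one assay, or a genes x
#'   samples matrix.
#' @return Tibble: `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    abort("no gene has nonzero counts in every sample; filter or pool samples")
  }
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu fitted to the
# per-gene method-of-moments estimates (least squares on genes with mu > 0)
fit_dispersion_trend <- function(mu, alpha_mom) {
  ok <- mu > 0 & is.finite(alpha_mom)
  if (sum(ok) < 10) return(function(m) pmax(mean(alpha_mom[ok]), 1e-8))
  fit <- lm(alpha_mom[ok] ~ I(1 / mu[ok]))
  a0 <- coef(fit)[[1]]; a1 <- coef(fit)[[2]]
  function(m) pmax(a0 + a1 / pmax(m, 1e-8), 1e-8)
}

#' Two-condition negative-binomial Wald test
#'
#' Counts are scaled by median-of-ratios size factors; per-gene dispersions
#' are estimated by method of moments, `alpha = max((s^2 - mu)/mu^2,
#' alpha_floor)` with the within-condition variances pooled, then shared
#' across genes through a parametric mean-dispersion trend `alpha(mu) = a0 +
#' a1/mu` (`dispersion = "trend"`, the default; `"max"` takes the more
#' conservative of trend and per-gene value, `"per-gene"` uses the raw
#' estimate). The test statistic is a Wald z on the log2 fold change with a
#' delta-method standard error from the NB variance `mu + alpha mu^2`;
#' two-sided p. A pseudocount of 0.5 is applied to the normalized condition
#' means for the fold change. Genes with all-zero counts get `log2fc = 0, p
#' = 1`.
#'
#' @param counts Output of [count_reads()] for one assay (2 conditions).
#' @param sf Optional size-factor tibble from [size_factors()].
#' @param dispersion One of `"trend"`, `"max"`, `"per-gene"`.
#' @param alpha_floor Lower bound on dispersion estimates.
#' @param ref Reference condition (denominator of the fold change); default
#'   `"control"` if present, else the first condition.
#' @return Tibble: `gene_id`, `base_mean`, `log2fc`, `p`.
#' @export
nb_test <- function(counts, sf = NULL, dispersion = c("trend", "max", "per-gene"),
                    alpha_floor = 1e-8, ref = NULL) {
  dispersion <- match.arg(dispersion)
  m <- count_matrix(counts)
  meta <- counts %>% distinct(.data$sample_id, .data$condition)
  cond <- setNames(meta$condition, meta$sample_id)[colnames(m)]
  levs <- unique(cond)
  if (length(levs) != 2) abort("nb_test needs exactly 2 conditions")
  ref <- ref %||% if ("control" %in% levs) "control" else levs[1]
  alt <- setdiff(levs, ref)

  sf <- sf %||% size_factors(m)
  s <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  z <- sweep(m, 2, s, "/")

  zA <- z[, cond == ref, drop = FALSE]
  zB <- z[, cond == alt, drop = FALSE]
  nA <- ncol(zA); nB <- ncol(zB)
  mA <- rowMeans(zA); mB <- rowMeans(zB); mu <- rowMeans(z)

  vA <- if (nA > 1) apply(zA, 1, var) else rep(NA_real_, nrow(z))
  vB <- if (nB > 1) apply(zB, 1, var) else rep(NA_real_, nrow(z))
  s2 <- rowMeans(cbind(vA, vB), na.rm = TRUE)
  a_mom <- pmax((s2 - mu) / pmax(mu, 1e-8)^2, alpha_floor)
  a_use <- switch(dispersion,
    "per-gene" = a_mom,
    "trend" = fit_dispersion_trend(mu, a_mom)(mu),
    "max" = pmax(a_mom, fit_dispersion_trend(mu, a_mom)(mu)))

  lfc <- log2((mB + 0.5) / (mA + 0.5))
  varA <- mA + a_use * mA^2
  varB <- mB + a_use * mB^2
  se <- sqrt((varA / (nA * (mA + 0.5)^2) + varB / (nB * (mB + 0.5)^2)) / log(2)^2)
  wald <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(wald))
  degenerate <- rowSums(m) == 0
  lfc[degenerate] <- 0
  p[degenerate | !is.finite(p)] <- 1
  tibble(gene_id = rownames(m), base_mean = mu, log2fc = unname(lfc),
         p = unname(p))
}

#' Three-way transcriptional / translational classification
#'
#' Benjamini-Hochberg adjustment is applied separately within each assay;
#' significance is `padj <= fdr`. Genes significant in both assays take
#' `both_up` / `both_down` when the fold changes agree in sign and
#' `discordant` otherwise; genes significant in one assay take the
#' `mrna_only` / `rpf_only` class of that assay's sign; the rest are
#' `unchanged`. Genes listed in `below_detection` are excluded from testing
#' and labelled as such.
#'
#' @param mrna_results,rpf_results [nb_test()] results on the same gene
#'   universe.
#' @param fdr False-discovery-rate threshold (0.1 in the classical design).
#' @param below_detection Optional character vector of gene ids under the
#'   spike-in detection limit in all samples.
#' @return Tibble: `gene_id`, `log2fc_mrna`, `p_mrna`, `padj_mrna`,
#'   `log2fc_rpf`, `p_rpf`, `padj_rpf`, `class`.
#' @export
classify_genes <- function(mrna_results, rpf_results, fdr = 0.1,
                           below_detection = character()) {
  d <- length(union(mrna_results$gene_id, rpf_results$gene_id)) -
    length(intersect(mrna_results$gene_id, rpf_results$gene_id))
  if (d > 0) {
    abort(sprintf("mRNA and RPF results differ in %d gene ids", d))
  }
  keep_m <- mrna_results %>% filter(!.data$gene_id %in% below_detection) %>%
    mutate(padj = p.adjust(.data$p, "BH"))
  keep_r <- rpf_results %>% filter(!.data$gene_id %in% below_detection) %>%
    mutate(padj = p.adjust(.data$p, "BH"))
  res <- keep_m %>%
    select("gene_id", log2fc_mrna = "log2fc", p_mrna = "p", padj_mrna = "padj") %>%
    inner_join(keep_r %>% select("gene_id", log2fc_rpf = "log2fc",
                                 p_rpf = "p", padj_rpf = "padj"),
               by = "gene_id") %>%
    mutate(
      sig_m = .data$padj_mrna <= fdr,
      sig_r = .data$padj_rpf <= fdr,
      class = case_when(
        .data$sig_m & .data$sig_r &
          sign(.data$log2fc_mrna) != sign(.data$log2fc_rpf) ~ "discordant",
        .data$sig_m & .data$sig_r & .data$log2fc_mrna > 0 ~ "both_up",
        .data$sig_m & .data$sig_r ~ "both_down",
        .data$sig_m & .data$log2fc_mrna > 0 ~ "mrna_only_up",
        .data$sig_m ~ "mrna_only_down",
        .data$sig_r & .data$log2fc_rpf > 0 ~ "rpf_only_up",
        .data$sig_r ~ "rpf_only_down",
        TRUE ~ "unchanged")) %>%
    select(-"sig_m", -"sig_r")
  if (length(below_detection) > 0) {
    res <- bind_rows(res, tibble(
      gene_id = intersect(mrna_results$gene_id, below_detection),
      log2fc_mrna = NA_real_, p_mrna = NA_real_, padj_mrna = NA_real_,
      log2fc_rpf = NA_real_, p_rpf = NA_real_, padj_rpf = NA_real_,
      class = "below_detection"))
  }
  arrange(res, .data$gene_id)
}

#' End-to-end differential analysis of a paired RNA/RPF experiment
#'
#' Runs [nb_test()] on the mRNA and RPF count sets, applies the spike-in
#' detection limit when supplied, and classifies every gene.
#'
#' @param counts Output of [count_reads()] containing both assays.
#' @param fdr FDR threshold.
#' @param limits Optional [detection_limit()] output; genes whose rpkm is
#'   below the (mean) threshold in every sample are excluded.
#' @param ... Passed to [nb_test()].
#' @return Object of class `riboheat_diffexpr` with elements `results`,
#'   `fdr`, `n_tested`, `n_below_detection`.
#' @export
translatome_diffexpr <- function(counts, fdr = 0.1, limits = NULL, ...) {
  below <- character()
  if (!is.null(limits)) {
    thr <- limits %>% filter(!.data$flagged)
    if (nrow(thr) > 0) {
      rpkm <- normalize_counts(counts, "rpkm") %>%
        left_join(thr %>% select("sample_id", "threshold_rpkm"),
                  by = "sample_id")
      below <- rpkm %>%
        filter(!is.na(.data$threshold_rpkm)) %>%
        group_by(.data$gene_id) %>%
        summarise(below = all(.data$rpkm < .data$threshold_rpkm),
                  .groups = "drop") %>%
        filter(.data$below) %>% pull("gene_id")
    }
  }
  res_m <- nb_test(counts %>% filter(.data$assay == "rna"), ...)
  res_r <- nb_test(counts %>% filter(.data$assay == "rpf"), ...)
  results <- classify_genes(res_m, res_r, fdr = fdr, below_detection = below)
  structure(list(results = results, fdr = fdr,
                 n_tested = sum(results$class != "below_detection"),
                 n_below_detection = length(below)),
            class = "riboheat_diffexpr")
}

#' @export
print.riboheat_diffexpr <- function(x, ...) {
  cat(sprintf("riboheat differential analysis: %d genes tested (FDR %.2g), %d below detection\n",
              x$n_tested, x$fdr, x$n_below_detection))
  print(dplyr::count(x$results, .data$class))
  invisible(x)
}

#' Broom-style accessors for a differential analysis
#'
#' `tidy()` returns the per-gene table; `glance()` one row of class counts.
#'
#' @param x A `riboheat_diffexpr`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.riboheat_diffexpr <- function(x, ...) x$results

#' @rdname tidy.riboheat_diffexpr
#' @export
glance.riboheat_diffexpr <- function(x, ...) {
  cls <- table(x$results$class)
  bind_cols(tibble(n_tested = x$n_tested, fdr = x$fdr,
                   n_below_detection = x$n_below_detection),
            as_tibble(as.list(cls)))
}
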