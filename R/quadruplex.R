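tier_runlen <- function(tier) {
  k <- c(G2 = 2L, G3 = 3L, G4 = 4L)[[tier]]
  if (is.null(k)) abort(sprintf("unknown tier '%s'", tier))
  k
}

# scan one sequence for one tier; returns tibble(start, end, match), 0-based
# half-open. In "anchored" mode (default) one lazy-loop match is attempted at
# the first position of every maximal G-run of length >= tier; in "all" mode
# a match is attempted at every position opening a run of >= tier Gs.
scan_sequence <- function(seq, tier, mode = c("anchored", "all")) {
  mode <- match.arg(mode)
  k <- tier_runlen(tier)
  # first run is lazy-elastic (G{k,}?): a maximal run longer than the tier
  # satisfies the run requirement while the hit stays anchored at the run's
  # first position; loops are lazy, so the leftmost/shortest decomposition
  # wins
  pat <- paste0("^G{", k, ",}?[ACGT]{1,7}?",
                paste(rep(strrep("G", k), 3), collapse = "[ACGT]{1,7}?"))
  empty <- tibble(start = integer(), end = integer(), match = character())
  runs <- gregexpr("G+", seq)[[1]]
  if (runs[1] == -1) return(empty)
  starts <- as.integer(runs)
  lens <- attr(runs, "match.length")
  ok <- lens >= k
  if (!any(ok)) return(empty)
  if (mode == "anchored") {
    anchors <- starts[ok]
    runlen <- lens[ok]
  } else {
    anchors <- unlist(purrr::map2(starts[ok], lens[ok],
                                  function(s, l) s:(s + l - k)))
    runlen <- unlist(purrr::map(lens[ok], function(l) l:k))
  }
  # a match spans at most the first run plus three loops and three runs
  span <- runlen + 3L * (7L + k)
  windows <- substr(rep(seq, length(anchors)), anchors,
                    pmin(anchors + span - 1L, nchar(seq)))
  m <- regexpr(pat, windows, perl = TRUE)
  found <- m != -1L
  if (!any(found)) return(empty)
  len <- attr(m, "match.length")[found]
  a <- anchors[found]
  tibble(start = a - 1L, end = a - 1L + len,
         match = substr(rep(seq, length(a)), a, a + len - 1L))
}

#' Scan transcripts for G-quadruplex-forming sequences
#'
#' Matches the grammar `Gk N1-7 Gk N1-7 Gk N1-7 Gk` for tiers G2 (k = 2), G3
#' (k = 3) and G4 (k = 4); tiers are scanned independently. Matches are
#' leftmost-starting and loop-lazy (shortest loops first); each first-G-run
#' anchor yields at most one hit, and a longer G-run satisfies a shorter
#' tier's run requirement with the run's first position as anchor. A hit's
#' region (5'UTR / CDS / 3'UTR) is the region containing its start.
#'
#' @param models Transcript model tibble.
#' @param tiers Character vector of tiers to scan.
#' @param mode `"anchored"` (one hit per G-run anchor, default) or `"all"`
#'   (every position opening a sufficient G-run is tried).
#' @return Tibble: `gene_id`, `tier`, `region`, `start`, `end`, `match`
#'   (transcript coordinates, 0-based half-open).
#' @export
scan_quadruplexes <- function(models, tiers = c("G2", "G3", "G4"),
                              mode = c("anchored", "all")) {
  mode <- match.arg(mode)
  assert_models(models)
  out <- purrr::map(tiers, function(tier) {
    per_gene <- purrr::pmap(
      list(models$gene_id, models$sequence),
      function(g, sq) {
        h <- scan_sequence(sq, tier, mode)
        if (nrow(h) == 0) return(NULL)
        h$gene_id <- g
        h
      })
    bind_rows(per_gene) %>% mutate(tier = tier)
  })
  hits <- bind_rows(out)
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), tier = character(),
                  region = character(), start = integer(), end = integer(),
                  match = character()))
  }
  hits %>%
    left_join(models %>% select("gene_id", "cds_start", "cds_end", "length"),
              by = "gene_id") %>%
    mutate(region = case_when(.data$start < .data$cds_start ~ "utr5",
                              .data$start < .data$cds_end ~ "cds",
                              TRUE ~ "utr3")) %>%
    select("gene_id", "tier", "region", "start", "end", "match") %>%
    arrange(.data$gene_id, .data$tier, .data$start)
}

#' Ribosome-footprint metaprofile flanking quadruplex starts
#'
#' For each hit gene and each position in `[-flank[1], +flank[2])` relative
#' to the first base of the quadruplex, computes the RPF read density (rpm,
#' replicates pooled per condition) divided by the mRNA read count at the
#' same position (floored at `pseudocount`). Reads contribute at their
#' 5'-end position — the single-nucleotide assignment conventional for
#' footprint metaprofiles — which keeps neighbouring positions
#' statistically independent. Genes with several hits in the supplied class
#' contribute the average of their per-hit values (equal gene weighting);
#' positions outside the transcript are missing and excluded from that
#' gene's contribution. Conditions are compared by a two-sided Wilcoxon
#' signed-rank test on the paired per-position metaprofile values after
#' dividing each gene's curve by the gene's CDS-level RPF/mRNA ratio in the
#' same units: without that per-gene normalization, library-size and
#' per-gene expression noise move whole curves coherently and the paired
#' test rejects under the null. If every paired difference
#' is zero the p-value is 1 by convention. Raw ratio curves and
#' cumulative-sum curves are emitted alongside the shape-normalized means.
#'
#' @param hits [scan_quadruplexes()] rows of one tier/region class.
#' @param reads Read tibble with both assays and conditions.
#' @param models Transcript model tibble.
#' @param flank Upstream/downstream extents (nt) around the hit start.
#' @param pseudocount Floor for the per-position mRNA read count.
#' @param min_genes Minimum genes contributing on both sides for a position
#'   to enter the condition test (sparse positions have far larger
#'   variance).
#' @return Object of class `riboheat_flank`: `profile` (position,
#'   mean_control, mean_heat, norm_control, norm_heat, cum_control,
#'   cum_heat, n_control, n_heat), `test` (statistic, p, n_positions),
#'   `n_genes`.
#' @export
flank_metaprofile <- function(hits, reads, models, flank = c(200L, 250L),
                              pseudocount = 1, min_genes = 5L) {
  if (nrow(hits) == 0) {
    return(structure(list(profile = tibble(), test = list(statistic = NA_real_,
                                                          p = NA_real_,
                                                          n_positions = 0L),
                          n_genes = 0L), class = "riboheat_flank"))
  }
  genes <- unique(hits$gene_id)
  mods <- models %>% filter(.data$gene_id %in% genes)
  rel <- seq(-flank[1], flank[2] - 1L)

  # each read contributes at its 5'-end position (the single-nucleotide
  # assignment conventional for footprint metaprofiles); unlike span
  # coverage this keeps neighbouring positions independent, which the
  # paired per-position test relies on
  end_counts <- function(rds, tx, L) {
    p <- rds$pos[rds$transcript_id == tx]
    p <- p[p >= 0 & p < L]
    tabulate(p + 1L, nbins = L)
  }
  per_condition <- purrr::map(c("control", "heat"), function(cond) {
    rpf <- reads %>% filter(.data$assay == "rpf", .data$condition == cond)
    rna <- reads %>% filter(.data$assay == "rna", .data$condition == cond)
    scale_rpm <- 1e6 / max(nrow(rpf), 1)
    gene_vals <- purrr::map(genes, function(g) {
      m <- mods %>% filter(.data$gene_id == g)
      d_rpf <- end_counts(rpf, m$transcript_id, m$length)
      d_rna <- end_counts(rna, m$transcript_id, m$length)
      gh <- hits %>% filter(.data$gene_id == g)
      vals <- purrr::map(gh$start, function(s) {
        pos <- s + rel
        ok <- pos >= 0 & pos < m$length
        v <- rep(NA_real_, length(rel))
        v[ok] <- d_rpf[pos[ok] + 1L] * scale_rpm /
          pmax(d_rna[pos[ok] + 1L], pseudocount)
        v
      })
      # equal gene weighting: average this gene's hits first
      curve <- colMeans(do.call(rbind, vals), na.rm = TRUE)
      # RPF positional share for the condition test: the fraction of the
      # gene's footprints starting at each flank position (scaled by
      # transcript length so a uniform gene sits at 1). As a multinomial
      # proportion it cancels library size and the gene's expression level
      # exactly, so the paired per-position test is calibrated; the
      # mRNA-ratio curve above stays the displayed quantity
      U <- sum(d_rpf)
      shares <- purrr::map(gh$start, function(s) {
        pos <- s + rel
        ok <- pos >= 0 & pos < m$length
        v <- rep(NA_real_, length(rel))
        if (U > 0) v[ok] <- d_rpf[pos[ok] + 1L] / U * m$length
        v
      })
      list(curve = curve,
           norm = colMeans(do.call(rbind, shares), na.rm = TRUE))
    })
    mat <- do.call(rbind, purrr::map(gene_vals, "curve"))
    nmat <- do.call(rbind, purrr::map(gene_vals, "norm"))
    list(mat = mat, nmat = nmat)
  })
  summarize_mat <- function(mat) {
    m <- colMeans(mat, na.rm = TRUE)
    ifelse(is.nan(m), NA, m)
  }
  prof <- tibble(position = rel,
                 mean_control = summarize_mat(per_condition[[1]]$mat),
                 mean_heat = summarize_mat(per_condition[[2]]$mat),
                 norm_control = summarize_mat(per_condition[[1]]$nmat),
                 norm_heat = summarize_mat(per_condition[[2]]$nmat),
                 n_control = colSums(!is.na(per_condition[[1]]$mat)),
                 n_heat = colSums(!is.na(per_condition[[2]]$mat))) %>%
    mutate(cum_control = cumsum(dplyr::coalesce(.data$mean_control, 0)),
           cum_heat = cumsum(dplyr::coalesce(.data$mean_heat, 0)))

  # the condition test only uses positions supported by enough genes:
  # sparsely covered positions (e.g. upstream of most transcripts' 5' ends)
  # carry order-of-magnitude larger variance and would swamp the ranks
  paired <- prof %>% filter(!is.na(.data$norm_control),
                            !is.na(.data$norm_heat),
                            .data$n_control >= min_genes,
                            .data$n_heat >= min_genes)
  test <- signed_rank_test(paired$norm_heat, paired$norm_control)
  test$n_positions <- nrow(paired)
  structure(list(profile = prof, test = test, n_genes = length(genes)),
            class = "riboheat_flank")
}

# paired two-sided Wilcoxon signed-rank; all-zero differences -> p = 1
signed_rank_test <- function(x, y) {
  d <- x - y
  if (length(d) == 0 || all(d == 0)) {
    return(list(statistic = NA_real_, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

# signed-rank on median-centred paired differences: any global offset of
# one curve (library scale, shared normalizer noise) is removed before
# ranking, so the test targets localized enrichment; a median is robust to
# an elevation covering a minority of positions
centered_signed_rank_test <- function(x, y) {
  d <- x - y
  if (length(d) == 0 || all(d == 0)) {
    return(list(statistic = NA_real_, p = 1))
  }
  d <- d - median(d)
  wt <- suppressWarnings(wilcox.test(d, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' @export
print.riboheat_flank <- function(x, ...) {
  cat(sprintf("riboheat flanking metaprofile: %d gene(s), signed-rank p = %.3g over %d positions\n",
              x$n_genes, x$test$p, x$test$n_positions))
  invisible(x)
}

#' Fold-change association of 5'UTR quadruplex genes
#'
#' Splits genes carrying at least one hit of the requested tier/region into
#' translationally upregulated (`rpf_up`: significant RPF increase) vs
#' unchanged-or-down (`rpf_0_down`) and compares their CDS RPF log2 fold
#' changes with a two-sided Mann-Whitney test.
#'
#' @param hits [scan_quadruplexes()] output.
#' @param diff_results Per-gene table from [classify_genes()] /
#'   `tidy(translatome_diffexpr(...))`.
#' @param tier,region Hit class to consider.
#' @return A list: `groups` (gene_id, group, log2fc_rpf), `n_up`, `n_0_down`,
#'   `p` (NA when a group is empty).
#' @export
quadruplex_fold_change_association <- function(hits, diff_results,
                                               tier = "G2", region = "utr5") {
  g <- hits %>%
    filter(.data$tier == !!tier, .data$region == !!region) %>%
    distinct(.data$gene_id) %>%
    inner_join(diff_results, by = "gene_id") %>%
    filter(.data$class != "below_detection") %>%
    mutate(group = if_else(.data$class %in% c("rpf_only_up", "both_up"),
                           "rpf_up", "rpf_0_down")) %>%
    select("gene_id", "group", "log2fc_rpf")
  n_up <- sum(g$group == "rpf_up"); n_dn <- sum(g$group == "rpf_0_down")
  p <- NA_real_
  if (n_up > 0 && n_dn > 0) {
    p <- suppressWarnings(wilcox.test(
      g$log2fc_rpf[g$group == "rpf_up"],
      g$log2fc_rpf[g$group == "rpf_0_down"], exact = FALSE))$p.value
  }
  list(groups = g, n_up = n_up, n_0_down = n_dn, p = p)
}

#' mRNA half-read stability check for 3'UTR quadruplex genes
#'
#' For genes with a quadruplex in the 3'UTR, compares the first-half mRNA
#' read fraction between control and heat (paired per gene, Wilcoxon
#' signed-rank): an unchanged fraction argues against condition-specific
#' 3'-degradation.
#'
#' @param hits [scan_quadruplexes()] output (rows with `region == "utr3"`
#'   are used).
#' @param reads Read tibble.
#' @param models Transcript model tibble.
#' @param min_reads Passed to [half_symmetry()].
#' @return A list: `per_gene` (gene_id, frac_control, frac_heat, diff),
#'   `statistic`, `p`, `n`.
#' @export
utr3_half_reads_check <- function(hits, reads, models, min_reads = 32L) {
  genes <- hits %>% filter(.data$region == "utr3") %>% distinct(.data$gene_id)
  sym <- half_symmetry(reads %>% filter(.data$assay == "rna"), models,
                       min_reads = min_reads) %>%
    inner_join(genes, by = "gene_id")
  wide <- sym %>%
    select("gene_id", "condition", "frac_first") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "frac_first",
                       names_prefix = "frac_") %>%
    filter(!is.na(.data$frac_control), !is.na(.data$frac_heat)) %>%
    mutate(diff = .data$frac_heat - .data$frac_control)
  test <- signed_rank_test(wide$frac_heat, wide$frac_control)
  list(per_gene = wide, statistic = test$statistic, p = test$p,
       n = nrow(wide))
}
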