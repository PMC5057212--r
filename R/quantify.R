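#' Count reads per gene by the midpoint rule
#'
#' A read is assigned to a region iff its midpoint
#' (`five_prime_pos + floor(length / 2)`) lies in that region; each read is
#' counted at most once. The per-sample total mapped reads (all reads on
#' known transcripts, regardless of region) is carried along for
#' normalization, as is the counted region length per gene.
#'
#' @param reads Read tibble (any number of samples).
#' @param models Transcript model tibble.
#' @param region One of `"cds"`, `"utr5"`, `"utr3"`, `"full"`.
#' @return Long tibble: `gene_id`, `sample_id`, `assay`, `condition`,
#'   `replicate`, `region`, `count`, `region_len`, `total` (zero-count genes
#'   included).
#' @export
count_reads <- function(reads, models, region = c("cds", "utr5", "utr3", "full")) {
  region <- match.arg(region)
  assert_models(models)
  assert_reads(reads)
  reads <- reads %>% filter(.data$transcript_id %in% models$transcript_id)
  samples <- reads %>%
    group_by(.data$sample_id, .data$assay, .data$condition, .data$replicate) %>%
    summarise(total = dplyr::n(), .groups = "drop")

  bounds <- models %>%
    mutate(lo = switch(region, cds = .data$cds_start, utr5 = .data$utr5_start,
                       utr3 = .data$utr3_start, full = 0L),
           hi = switch(region, cds = .data$cds_end, utr5 = .data$utr5_end,
                       utr3 = .data$utr3_end, full = .data$length),
           region_len = .data$hi - .data$lo) %>%
    select("gene_id", "transcript_id", "lo", "hi", "region_len")

  counted <- reads %>%
    left_join(bounds, by = "transcript_id") %>%
    mutate(mid = .data$pos + .data$length %/% 2L) %>%
    filter(.data$mid >= .data$lo, .data$mid < .data$hi) %>%
    count(.data$gene_id, .data$sample_id, name = "count")

  tidyr::expand_grid(gene_id = models$gene_id, sample_id = samples$sample_id) %>%
    left_join(counted, by = c("gene_id", "sample_id")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    left_join(samples, by = "sample_id") %>%
    left_join(bounds %>% select("gene_id", "region_len"), by = "gene_id") %>%
    mutate(region = region) %>%
    select("gene_id", "sample_id", "assay", "condition", "replicate",
           "region", "count", "region_len", "total")
}

#' Pivot a long count tibble into a genes x samples matrix
#'
#' @param counts Output of [count_reads()].
#' @return Integer matrix, genes in rows.
#' @export
count_matrix <- function(counts) {
  wide <- counts %>%
    select("gene_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene_id
  m
}

#' rpm / rpkm normalization
#'
#' `rpm = count / total * 1e6`; `rpkm = count / (region_len/1e3 * total/1e6)`.
#' Spike-in reads are not part of the gene totals (they are normalized
#' separately by [spikein_rpkm()], mirroring standards that do not align to
#' the genome).
#'
#' @param counts Output of [count_reads()].
#' @param mode `"rpm"` or `"rpkm"`.
#' @return `counts` with the normalized column added.
#' @export
normalize_counts <- function(counts, mode = c("rpkm", "rpm")) {
  mode <- match.arg(mode)
  bad <- counts %>% filter(.data$total <= 0) %>% pull("sample_id") %>% unique()
  if (length(bad) > 0) {
    abort(paste0("zero total mapped reads in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (mode == "rpm") {
    counts %>% mutate(rpm = .data$count / .data$total * 1e6)
  } else {
    counts %>% mutate(rpkm = .data$count * 1e9 /
                        (.data$region_len * .data$total))
  }
}

#' Observed spike-in rpkm per RNA sample
#'
#' Spike-ins participate in the library total together with the gene reads of
#' the same sample (their own normalization only; gene rpkm excludes them).
#'
#' @param spikeins Spike-in count tibble from [simulate_reads()] (columns
#'   `spikein_id`, `sample_id`, `concentration`, `count`, `length`).
#' @param reads Read tibble used to derive per-sample gene totals.
#' @return `spikeins` with an `rpkm` column.
#' @export
spikein_rpkm <- function(spikeins, reads) {
  gene_tot <- reads %>% count(.data$sample_id, name = "gene_total")
  spike_tot <- spikeins %>%
    group_by(.data$sample_id) %>%
    summarise(spike_total = sum(.data$count), .groups = "drop")
  spikeins %>%
    left_join(gene_tot, by = "sample_id") %>%
    left_join(spike_tot, by = "sample_id") %>%
    mutate(gene_total = dplyr::coalesce(.data$gene_total, 0L),
           lib_total = .data$gene_total + .data$spike_total,
           rpkm = .data$count * 1e9 / (.data$length * .data$lib_total)) %>%
    select(-"gene_total", -"spike_total")
}

#' Detection limit from the spike-in ladder
#'
#' Fits a least-squares line to log observed rpkm vs log known concentration
#' over the upper half of the ladder, then walks down the ladder and reports
#' the observed rpkm of the lowest spike-in still within `tolerance` residual
#' standard deviations of the line. Genes whose rpkm never reaches the
#' threshold are not reliably detected.
#'
#' @param spikeins Tibble with `sample_id`, `spikein_id`, `concentration`,
#'   `rpkm` (see [spikein_rpkm()]).
#' @param tolerance Residual tolerance in units of the fit's residual SD.
#' @return Tibble: `sample_id`, `threshold_rpkm`, `n_within`, `flagged`,
#'   `note`.
#' @export
detection_limit <- function(spikeins, tolerance = 2) {
  one <- function(df, sample_id) {
    df <- df %>% arrange(dplyr::desc(.data$concentration))
    if (all(df$rpkm == 0) || nrow(df) < 4) {
      return(tibble(sample_id = sample_id, threshold_rpkm = NA_real_,
                    n_within = 0L, flagged = TRUE,
                    note = "all spike-ins zero or ladder too short"))
    }
    upper <- df %>%
      filter(.data$rpkm > 0) %>%
      filter(.data$concentration >= median(df$concentration))
    fit <- lm(log(rpkm) ~ log(concentration), data = upper)
    rsd <- max(sd(stats::residuals(fit)), 1e-9)
    pred <- coef(fit)[1] + coef(fit)[2] * log(df$concentration)
    res <- ifelse(df$rpkm > 0, log(df$rpkm) - pred, Inf)
    within <- abs(res) <= tolerance * rsd + 1e-9
    # walk down from the top of the ladder until the line breaks
    n_ok <- if (all(within)) nrow(df) else which(!within)[1] - 1L
    if (n_ok == 0) {
      return(tibble(sample_id = sample_id, threshold_rpkm = NA_real_,
                    n_within = 0L, flagged = TRUE,
                    note = "no spike-in on the fitted line"))
    }
    tibble(sample_id = sample_id, threshold_rpkm = df$rpkm[n_ok],
           n_within = n_ok, flagged = FALSE, note = NA_character_)
  }
  spikeins %>%
    group_by(.data$sample_id) %>%
    dplyr::group_map(~ one(.x, .y$sample_id)) %>%
    bind_rows()
}

#' Half-transcript symmetry of read counts
#'
#' Splits each CDS at `floor(len/2)` (first half takes the shorter side on
#' odd lengths), assigns reads by the midpoint rule, and reports the
#' first-half fraction per gene for each assay x condition (replicates
#' pooled). Genes with fewer than `min_reads` CDS reads in a cohort are
#' dropped from that cohort.
#'
#' @param reads Read tibble.
#' @param models Transcript model tibble.
#' @param min_reads Minimum pooled CDS reads per gene and cohort.
#' @return Tibble: `gene_id`, `assay`, `condition`, `first_half`,
#'   `second_half`, `frac_first`.
#' @export
half_symmetry <- function(reads, models, min_reads = 32L) {
  assert_models(models)
  assert_reads(reads)
  splits <- models %>%
    mutate(split = .data$cds_start + (.data$cds_end - .data$cds_start) %/% 2L) %>%
    select("gene_id", "transcript_id", "cds_start", "cds_end", "split")
  reads %>%
    inner_join(splits, by = "transcript_id") %>%
    mutate(mid = .data$pos + .data$length %/% 2L) %>%
    filter(.data$mid >= .data$cds_start, .data$mid < .data$cds_end) %>%
    group_by(.data$gene_id, .data$assay, .data$condition) %>%
    summarise(first_half = sum(.data$mid < .data$split),
              second_half = sum(.data$mid >= .data$split), .groups = "drop") %>%
    mutate(total = .data$first_half + .data$second_half,
           frac_first = if_else(.data$total > 0,
                                .data$first_half / .data$total, NA_real_)) %>%
    filter(.data$total >= min_reads) %>%
    select("gene_id", "assay", "condition", "first_half", "second_half",
           "frac_first")
}
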