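#' Flag half-symmetry outliers
#'
#' Robust z-score (median/MAD) of the first-half fraction across the cohort;
#' genes with `|z|` above the threshold are flagged with their direction
#' (`second_half` when reads pile downstream). When the MAD is zero the SD
#' is used; when both are zero no outliers exist.
#'
#' @param symmetry Output of [half_symmetry()] for one assay x condition
#'   cohort (>= 20 genes recommended).
#' @param threshold Robust z threshold.
#' @return `symmetry` with `z`, `outlier`, `direction` columns.
#' @export
asymmetry_outliers <- function(symmetry, threshold = 4) {
  f <- symmetry$frac_first
  ctr <- median(f)
  scale <- mad(f)
  if (scale == 0) scale <- sd(f)
  if (is.na(scale) || scale == 0) {
    return(symmetry %>% mutate(z = 0, outlier = FALSE,
                               direction = NA_character_))
  }
  symmetry %>%
    mutate(z = (.data$frac_first - ctr) / scale,
           outlier = abs(.data$z) > threshold,
           direction = case_when(!.data$outlier ~ NA_character_,
                                 .data$z < 0 ~ "second_half",
                                 TRUE ~ "first_half"))
}

#' Single change-point in a coverage vector
#'
#' Finds the split maximizing the two-segment least-squares gain
#' (equivalently the maximal CUSUM deviation) and reports the step ratio
#' mean(after) / mean(before). A step ratio within `flat_fold` of 1 is
#' flagged `no_step`.
#'
#' @param depth Numeric per-position coverage vector (e.g. the CDS slice of
#'   a [coverage_from_reads()] track).
#' @param min_segment Minimum segment length on either side of the split.
#' @param flat_fold Fold-change below which the step is considered absent.
#' @param eps Floor for the before-mean in the ratio.
#' @return One-row tibble: `changepoint` (0-based position of the first
#'   point of the second segment), `step_ratio`, `gain`, `no_step`.
#' @export
find_changepoint <- function(depth, min_segment = 10L, flat_fold = 1.5,
                             eps = 1e-8) {
  n <- length(depth)
  if (n < 2 * min_segment || sum(depth) == 0) {
    return(tibble(changepoint = NA_integer_, step_ratio = 1, gain = 0,
                  no_step = TRUE))
  }
  cs <- cumsum(depth)
  tot <- cs[n]
  k <- seq(min_segment, n - min_segment)         # split after position k
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  gain <- k * (n - k) / n * (m1 - m2)^2          # SSE reduction of the split
  best <- which.max(gain)
  cp <- k[best]                                   # 0-based first index of segment 2
  ratio <- m2[best] / max(m1[best], eps)
  tibble(changepoint = as.integer(cp), step_ratio = ratio,
         gain = gain[best],
         no_step = abs(log2(max(ratio, eps))) < log2(flat_fold))
}

#' Call an alternative ORF downstream of a coverage change point
#'
#' Searches for the first ATG at an in-frame CDS position within
#' `[changepoint - slack[1], changepoint + slack[2]]`, translates to the
#' first in-frame stop (standard code), and reports peptide length and
#' charged-residue fractions (positive = K+R, negative = D+E).
#'
#' @param model One-row transcript model tibble.
#' @param changepoint Change-point position in CDS coordinates (0-based).
#' @param slack Search window around the change point (nt before, nt after).
#' @param condition Label recording where the step was detected.
#' @return One-row tibble: `gene_id`, `changepoint`, `alt_start` (CDS
#'   coordinate, `NA` when rejected), `peptide`, `peptide_len`,
#'   `frac_positive`, `frac_negative`, `runs_to_cds_end`, `status`.
#' @export
call_alt_orf <- function(model, changepoint, slack = c(30L, 60L),
                         condition = NA_character_) {
  stopifnot(nrow(model) == 1)
  cds <- substr(model$sequence, model$cds_start + 1, model$cds_end)
  if (changepoint < 0 || changepoint >= nchar(cds)) {
    abort("changepoint outside the CDS")
  }
  lo <- max(0L, changepoint - slack[1])
  hi <- min(nchar(cds) - 3L, changepoint + slack[2])
  frame_pos <- seq(3L * ceiling(lo / 3), hi, by = 3L)
  is_atg <- substring(cds, frame_pos + 1L, frame_pos + 3L) == "ATG"
  rejected <- tibble(gene_id = model$gene_id, changepoint = changepoint,
                     alt_start = NA_integer_, peptide = NA_character_,
                     peptide_len = NA_integer_, frac_positive = NA_real_,
                     frac_negative = NA_real_, runs_to_cds_end = NA,
                     condition = condition,
                     status = "no in-frame ATG in search window")
  if (!any(is_atg)) return(rejected)
  alt_start <- frame_pos[which(is_atg)[1]]
  tr <- translate_to_stop(substr(cds, alt_start + 1L, nchar(cds)))
  aa <- strsplit(tr$peptide, "")[[1]]
  n_aa <- length(aa)
  tibble(gene_id = model$gene_id, changepoint = changepoint,
         alt_start = as.integer(alt_start), peptide = tr$peptide,
         peptide_len = n_aa,
         frac_positive = if (n_aa > 0) mean(aa %in% c("K", "R")) else NA_real_,
         frac_negative = if (n_aa > 0) mean(aa %in% c("D", "E")) else NA_real_,
         runs_to_cds_end = !tr$hit_stop,
         condition = condition,
         status = if (tr$hit_stop) "ok" else "no stop before CDS end")
}

#' Scan a promoter region for a consensus element
#'
#' Reports every position where the sequence matches the consensus (with
#' `N` as wildcard) on either strand, allowing up to `max_mismatch`
#' mismatches outside wildcard positions. Minus-strand matches are reported
#' at the forward-strand position of the match's leftmost base.
#'
#' @param seq Upstream/promoter sequence (<= 1 kb typical), alphabet ACGT(N).
#' @param element Consensus, default the heat-shock element `AGAANNTTCT`.
#' @param max_mismatch Allowed mismatches at non-wildcard positions.
#' @return Tibble: `start` (0-based), `strand`, `match`.
#' @export
promoter_element_scan <- function(seq, element = "AGAANNTTCT",
                                  max_mismatch = 0L) {
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(element)
  one_strand <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch,
                                  fixed = FALSE)
    if (length(m) == 0) {
      return(tibble(start = integer(), strand = character(),
                    match = character()))
    }
    tibble(start = BiocGenerics::start(m) - 1L, strand = strand,
           match = as.character(m))
  }
  bind_rows(one_strand(pat, "+"),
            one_strand(Biostrings::reverseComplement(pat), "-")) %>%
    arrange(.data$start)
}

#' Select genes gaining UTR ribosome footprints under stress
#'
#' A gene from the candidate universe is selected when its UTR RPF rpm fold
#' change (heat / control, pseudocount 1 rpm) reaches `min_fc` and its heat
#' UTR read count reaches `min_reads`. Selected UTR sequences can be
#' exported as FASTA for external motif discovery; the motif-search
#' parameters are recorded as metadata on the result.
#'
#' @param reads Read tibble.
#' @param models Transcript model tibble.
#' @param universe Candidate gene ids (typically the translationally
#'   upregulated set).
#' @param region `"utr5"` or `"utr3"`.
#' @param min_fc rpm fold-change threshold.
#' @param min_reads Minimum heat-condition UTR reads.
#' @param fasta_out Optional path; when given, the selected UTR sequences are
#'   written as FASTA.
#' @return Tibble of selected genes (`gene_id`, `rpm_control`, `rpm_heat`,
#'   `fold_change`, `heat_reads`) with a `motif_params` attribute.
#' @export
select_utr_rpf_gain_genes <- function(reads, models, universe,
                                      region = c("utr5", "utr3"),
                                      min_fc = 2, min_reads = 10L,
                                      fasta_out = NULL) {
  region <- match.arg(region)
  mods <- models %>% filter(.data$gene_id %in% universe)
  has_utr <- if (region == "utr5") mods$utr5_end > mods$utr5_start else
    mods$utr3_end > mods$utr3_start
  mods <- mods[has_utr, ]
  empty <- tibble(gene_id = character(), rpm_control = double(),
                  rpm_heat = double(), fold_change = double(),
                  heat_reads = integer())
  rpf <- reads %>% filter(.data$assay == "rpf")
  if (nrow(rpf) == 0 || nrow(mods) == 0) return(empty)
  cnt <- count_reads(rpf, mods, region = region) %>%
    normalize_counts("rpm") %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(rpm = mean(.data$rpm), reads = sum(.data$count),
              .groups = "drop")
  if (!all(c("control", "heat") %in% cnt$condition)) return(empty)
  sel <- cnt %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("rpm", "reads")) %>%
    mutate(across(dplyr::starts_with("rpm_"), ~ dplyr::coalesce(.x, 0)),
           across(dplyr::starts_with("reads_"), ~ dplyr::coalesce(.x, 0L)),
           fold_change = (.data$rpm_heat + 1) / (.data$rpm_control + 1)) %>%
    filter(.data$fold_change >= min_fc, .data$reads_heat >= min_reads) %>%
    select("gene_id", "rpm_control", "rpm_heat", fold_change = "fold_change",
           heat_reads = "reads_heat")
  if (!is.null(fasta_out) && nrow(sel) > 0) {
    m <- mods %>% filter(.data$gene_id %in% sel$gene_id)
    utr <- if (region == "utr5") {
      substring(m$sequence, m$utr5_start + 1, m$utr5_end)
    } else {
      substring(m$sequence, m$utr3_start + 1, m$utr3_end)
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(utr, m$gene_id)), fasta_out)
  }
  attr(sel, "motif_params") <- list(tool = "MEME", min_width = 6,
                                    max_width = 20, max_motifs = 10,
                                    site_model = "zero or one per sequence")
  sel
}
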