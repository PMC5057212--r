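#' Folding energy of a short RNA sequence
#'
#' Exact optimum of a weighted base-pair maximization model (Nussinov-style
#' dynamic program): nested structures only, pair weights G-C = 3, A-U = 2,
#' G-U = 1, minimum hairpin loop of 3 unpaired nt, score reported negated so
#' that more negative = more stable. T is read as U. This is a self-contained
#' pair-richness model, not a thermodynamic nearest-neighbour model; an
#' external folding backend can be substituted through the `backend` seam of
#' [mfe_profile()].
#'
#' @param seq Character vector of sequences (alphabet ACGU/T).
#' @param minloop Minimum unpaired hairpin loop length.
#' @return Numeric vector of energies (<= 0, arbitrary units).
#' @export
fold_mfe <- function(seq, minloop = 3L) {
  stopifnot(is.character(seq))
  fold_mfe_cpp(seq, as.integer(minloop))
}

#' Sliding-window folding-energy profile around start codons
#'
#' For each position `c` in `span` (relative to the start codon; position 0
#' is the first nucleotide of the ATG), folds the `window`-nt window centred
#' at `c` and assigns its minimum free energy to `c`. Windows extending past
#' a transcript end are undefined (`NA`).
#'
#' @param models Transcript model tibble.
#' @param span Two integers, relative window-centre range (default -150..150).
#' @param window Window width in nt (odd; default 39).
#' @param backend Folding backend: a function `(character vector) -> numeric`
#'   scoring whole windows. Defaults to the built-in [fold_mfe()].
#' @return Tibble: `gene_id`, `position`, `energy`, with attribute `backend`.
#' @export
mfe_profile <- function(models, span = c(-150L, 150L), window = 39L,
                        backend = NULL) {
  assert_models(models)
  if (window %% 2 != 1) abort("window must be odd")
  rel <- span[1]:span[2]
  backend_name <- if (is.null(backend)) "builtin-nussinov" else "custom"
  out <- purrr::pmap(
    list(models$gene_id, models$sequence, models$cds_start),
    function(g, sq, cds_start) {
      if (nchar(sq) < window) {
        return(tibble(gene_id = character(), position = integer(),
                      energy = double()))
      }
      centers <- cds_start + rel
      e <- if (is.null(backend)) {
        window_mfe_cpp(sq, as.integer(centers), as.integer(window), 3L)
      } else {
        half <- (window - 1L) %/% 2L
        ok <- centers - half >= 0 & centers + half < nchar(sq)
        v <- rep(NA_real_, length(centers))
        if (any(ok)) {
          w <- substring(sq, centers[ok] - half + 1L, centers[ok] + half + 1L)
          v[ok] <- backend(w)
        }
        v
      }
      tibble(gene_id = g, position = rel, energy = e)
    })
  out <- bind_rows(out) %>% filter(!is.na(.data$energy))
  attr(out, "backend") <- backend_name
  out
}

#' Group metaprofiles and the upstream-region test
#'
#' Averages per-position folding energies across the genes of each group and
#' compares groups on the per-gene mean energy over `region` (default
#' -100..0, the window upstream of the start codon) with a two-sided
#' two-sample Mann-Whitney U test. Groups of fewer than 3 genes are skipped
#' with a warning.
#'
#' @param profiles Output of [mfe_profile()].
#' @param groups Tibble: `gene_id`, `group` (disjoint gene sets).
#' @param region Two integers, half-open position interval for the region
#'   statistic.
#' @return Object of class `riboheat_folding` with elements `profile`
#'   (group, position, mean, sd, n), `region_energy` (gene_id, group,
#'   mean_energy), `tests` (group pair, U, p), `region`.
#' @export
group_metaprofile <- function(profiles, groups, region = c(-100L, 0L)) {
  dup <- groups %>% count(.data$gene_id) %>% filter(n > 1)
  if (nrow(dup) > 0) abort("groups must be disjoint gene-id sets")
  prof <- profiles %>%
    inner_join(groups, by = "gene_id") %>%
    group_by(.data$group, .data$position) %>%
    summarise(mean = mean(.data$energy), sd = sd(.data$energy),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(sd = dplyr::coalesce(.data$sd, 0))

  region_energy <- profiles %>%
    inner_join(groups, by = "gene_id") %>%
    filter(.data$position >= region[1], .data$position < region[2]) %>%
    group_by(.data$gene_id, .data$group) %>%
    summarise(mean_energy = mean(.data$energy), .groups = "drop")

  grps <- unique(groups$group)
  tests <- list()
  if (length(grps) >= 2) {
    pairs <- utils::combn(grps, 2, simplify = FALSE)
    tests <- purrr::map(pairs, function(pr) {
      xa <- region_energy$mean_energy[region_energy$group == pr[1]]
      xb <- region_energy$mean_energy[region_energy$group == pr[2]]
      if (length(xa) < 3 || length(xb) < 3) {
        warn(sprintf("group pair %s/%s has < 3 genes; test skipped",
                     pr[1], pr[2]))
        return(tibble(group_a = pr[1], group_b = pr[2],
                      n_a = length(xa), n_b = length(xb),
                      U = NA_real_, p = NA_real_))
      }
      wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
      tibble(group_a = pr[1], group_b = pr[2], n_a = length(xa),
             n_b = length(xb), U = unname(wt$statistic), p = wt$p.value)
    })
  }
  structure(list(profile = prof, region_energy = region_energy,
                 tests = bind_rows(tests), region = region),
            class = "riboheat_folding")
}

#' @export
print.riboheat_folding <- function(x, ...) {
  cat(sprintf("riboheat folding metaprofile: %d group(s), region [%d, %d)\n",
              dplyr::n_distinct(x$profile$group), x$region[1], x$region[2]))
  if (nrow(x$tests) > 0) print(x$tests)
  invisible(x)
}
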