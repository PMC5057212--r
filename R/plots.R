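#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_ribbon
#'   geom_vline labs facet_wrap theme_minimal autoplot scale_colour_manual
NULL

#' Plot a folding-energy metaprofile
#'
#' One line per gene group; position 0 is the first nucleotide of the start
#' codon, more negative energies mean more pairing.
#'
#' @param object A `riboheat_folding` from [group_metaprofile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.riboheat_folding <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$position, y = .data$mean,
                             colour = .data$group)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = "position relative to start codon (nt)",
         y = "mean folding energy (a.u.)", colour = "group") +
    theme_minimal()
}

#' Plot a quadruplex-flanking RPF metaprofile
#'
#' RPF/mRNA ratio curves per condition; the quadruplex starts at position 0.
#'
#' @param object A `riboheat_flank` from [flank_metaprofile()].
#' @param cumulative Plot cumulative-sum curves instead of per-position
#'   means.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.riboheat_flank <- function(object, cumulative = FALSE, ...) {
  prof <- object$profile
  cols <- if (cumulative) c("cum_control", "cum_heat") else
    c("mean_control", "mean_heat")
  long <- prof %>%
    select("position", dplyr::all_of(cols)) %>%
    tidyr::pivot_longer(-"position", names_to = "condition",
                        values_to = "value") %>%
    mutate(condition = sub("^(cum|mean)_", "", .data$condition))
  ggplot(long, aes(x = .data$position, y = .data$value,
                   colour = .data$condition)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    scale_colour_manual(values = c(control = "#2166ac", heat = "#b2182b")) +
    labs(x = "position relative to quadruplex start (nt)",
         y = if (cumulative) "cumulative RPF/mRNA" else "RPF rpm / mRNA reads") +
    theme_minimal()
}

#' Class counts of a differential analysis
#'
#' Bar chart of the three-way regulation classes (the classical
#' transcriptional/translational partition).
#'
#' @param object A `riboheat_diffexpr`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.riboheat_diffexpr <- function(object, ...) {
  cls <- object$results %>% count(.data$class)
  ggplot(cls, aes(x = .data$class, y = .data$n)) +
    geom_col(fill = "grey30") +
    labs(x = NULL, y = "genes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Observed vs expected subunit ratios of a complex audit
#'
#' @param object A `riboheat_stoich`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.riboheat_stoich <- function(object, ...) {
  ggplot(object$subunits,
         aes(x = .data$gene_id, y = .data$obs_ratio, fill = .data$condition)) +
    geom_col(position = "dodge") +
    geom_point(aes(y = .data$exp_ratio), shape = 4, size = 3,
               show.legend = FALSE) +
    facet_wrap(~ .data$complex, scales = "free_x") +
    labs(x = NULL, y = "production ratio (vs lowest-stoichiometry subunit)",
         fill = NULL) +
    theme_minimal()
}
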