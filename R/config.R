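#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_transcriptome()] and
#' [simulate_reads()]. Defaults describe a two-condition (control vs heat),
#' two-replicate paired RNA-Seq/Ribo-Seq experiment on a toy transcriptome
#' with planted differential-expression classes, G-quadruplexes, one
#' alternative-ORF gene, an external spike-in ladder and a plastid operon set
#' with known subunit stoichiometry.
#'
#' @param seed Integer seed controlling all simulation randomness.
#' @param n_genes Number of nuclear genes (plastid genes from
#'   `plastid_complexes` are added on top).
#' @param n_per_class Named integer vector of planted class sizes over
#'   `both_up, both_down, mrna_only_up, mrna_only_down, rpf_only_up,
#'   rpf_only_down, null`. An `NA` for `null` is filled so sizes sum to
#'   `n_genes`.
#' @param utr5_len,cds_len,utr3_len Length ranges (nt) for the three
#'   transcript regions; CDS lengths are rounded to multiples of 3.
#' @param lfc_effect Planted log2 fold-change magnitude (> 0).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`).
#' @param depth Mean reads per gene per sample per assay.
#' @param lib_jitter Range of per-sample library-size factors.
#' @param read_len Read-length range (nt) for both assays (gel size selection
#'   keeps 25-35 nt fragments for RNA and ribosome-protected fragments alike).
#' @param n_quadruplex_genes Named vector: number of genes planted with a
#'   quadruplex per region class (`utr5`, `cds`, `utr3`).
#' @param quadruplex_tier Tier of the planted quadruplexes (`"G2"`, `"G3"`,
#'   `"G4"`).
#' @param quadruplex_boost Multiplicative elevation of stress-condition RPF
#'   read starts over planted UTR quadruplex windows.
#' @param altorf_gene Plant one alternative-ORF gene?
#' @param altorf_cds_len CDS length (nt, multiple of 3) of the alt-ORF gene.
#' @param altorf_changepoint CDS position (0-based) at which stress RPF
#'   coverage steps up.
#' @param altorf_peptide_len Length (aa) of the planted alternative peptide.
#' @param altorf_step Step ratio of RPF coverage after vs before the change
#'   point under stress.
#' @param altorf_kr_frac Fraction of positively charged residues (K+R) drawn
#'   for the planted peptide.
#' @param spikein_concentrations Ladder of known spike-in amounts (arbitrary
#'   units).
#' @param spikein_floor Concentration below which spike-in capture drops out
#'   (the planted detection floor).
#' @param spikein_scale Expected reads per concentration unit above the floor.
#' @param spikein_length Spike-in transcript length (nt).
#' @param structure_window Width (nt) of the upstream window, ending at the
#'   start codon, in which low-structure genes are drawn A/U rich.
#' @param gc_background,gc_low_structure GC content of background sequence and
#'   of the A/U-rich upstream window of the low-structure group
#'   (translationally upregulated genes).
#' @param plastid_complexes Tibble with columns `complex`, `gene_id`,
#'   `stoichiometry`, `operon_id` defining plastid protein complexes.
#' @param plastid_heat_scale Uniform scaling of plastid RPF output under heat.
#' @param plastid_disprop_gene Plastid gene whose production is additionally
#'   reduced under heat (set `NA` to disable).
#' @param plastid_disprop_factor Extra production factor applied to
#'   `plastid_disprop_gene` under heat. The default 0.4 places the planted
#'   fold-change spread (1/0.4 = 2.5) strictly beyond the audit's 2-fold
#'   flag threshold; an exactly halved subunit would sit on the threshold
#'   itself, where no detection rule can behave reliably.
#'
#' @return A list of class `riboheat_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       n_per_class = c(both_up = 15L, both_down = 15L,
                                       mrna_only_up = 15L, mrna_only_down = 15L,
                                       rpf_only_up = 30L, rpf_only_down = 15L,
                                       null = NA_integer_),
                       utr5_len = c(150L, 250L),
                       cds_len = c(300L, 1500L),
                       utr3_len = c(90L, 240L),
                       lfc_effect = 2,
                       dispersion = 0.05,
                       depth = 500,
                       lib_jitter = c(0.8, 1.25),
                       read_len = c(25L, 35L),
                       n_quadruplex_genes = c(utr5 = 30L, cds = 0L, utr3 = 30L),
                       quadruplex_tier = "G2",
                       quadruplex_boost = 3,
                       altorf_gene = TRUE,
                       altorf_cds_len = 2802L,
                       altorf_changepoint = 2195L,
                       altorf_peptide_len = 88L,
                       altorf_step = 8,
                       altorf_kr_frac = 0.4,
                       spikein_concentrations = 2^(0:7),
                       spikein_floor = 8,
                       spikein_scale = 8,
                       spikein_length = 1000L,
                       structure_window = 100L,
                       gc_background = 0.45,
                       gc_low_structure = 0.20,
                       plastid_complexes = default_plastid_complexes(),
                       plastid_heat_scale = 0.8,
                       plastid_disprop_gene = "atpH",
                       plastid_disprop_factor = 0.4) {
  classes <- c("both_up", "both_down", "mrna_only_up", "mrna_only_down",
               "rpf_only_up", "rpf_only_down", "null")
  n_per_class <- n_per_class[classes]
  names(n_per_class) <- classes
  n_per_class[is.na(n_per_class) & names(n_per_class) != "null"] <- 0L
  if (is.na(n_per_class[["null"]])) {
    n_per_class[["null"]] <- n_genes - sum(n_per_class[classes != "null"])
  }
  if (any(n_per_class < 0)) abort("class sizes must be >= 0 and sum to n_genes")
  if (sum(n_per_class) != n_genes) {
    abort(sprintf("class sizes sum to %d but n_genes = %d",
                  sum(n_per_class), n_genes))
  }
  if (lfc_effect <= 0) abort("lfc_effect must be > 0")
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (depth < 0) abort("depth must be >= 0")
  stopifnot(length(utr5_len) == 2, length(cds_len) == 2, length(utr3_len) == 2)
  nq <- c(utr5 = 0L, cds = 0L, utr3 = 0L)
  nq[names(n_quadruplex_genes)] <- n_quadruplex_genes
  if (altorf_gene) {
    if (altorf_cds_len %% 3 != 0) abort("altorf_cds_len must be a multiple of 3")
    alt_start <- 3L * ceiling(altorf_changepoint / 3)
    need <- alt_start + 3L * (altorf_peptide_len + 1L)
    if (need > altorf_cds_len) {
      abort(sprintf(paste0("infeasible config: alt-ORF of %d codons starting ",
                           "in-frame at/after %d needs a CDS of >= %d nt, got %d"),
                    altorf_peptide_len, altorf_changepoint, need, altorf_cds_len))
    }
  }
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_per_class = n_per_class,
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    lfc_effect = lfc_effect, dispersion = dispersion, depth = depth,
    lib_jitter = lib_jitter, read_len = as.integer(read_len),
    n_quadruplex_genes = nq, quadruplex_tier = quadruplex_tier,
    quadruplex_boost = quadruplex_boost,
    altorf_gene = isTRUE(altorf_gene), altorf_cds_len = as.integer(altorf_cds_len),
    altorf_changepoint = as.integer(altorf_changepoint),
    altorf_peptide_len = as.integer(altorf_peptide_len),
    altorf_step = altorf_step, altorf_kr_frac = altorf_kr_frac,
    spikein_concentrations = spikein_concentrations,
    spikein_floor = spikein_floor, spikein_scale = spikein_scale,
    spikein_length = as.integer(spikein_length),
    structure_window = as.integer(structure_window),
    gc_background = gc_background, gc_low_structure = gc_low_structure,
    plastid_complexes = plastid_complexes,
    plastid_heat_scale = plastid_heat_scale,
    plastid_disprop_gene = plastid_disprop_gene,
    plastid_disprop_factor = plastid_disprop_factor
  )
  structure(cfg, class = "riboheat_config")
}

#' Default plastid complex definitions
#'
#' A simplified chloroplast ATP synthase with its two operons: one carrying a
#' 3:1:1:1 subunit stoichiometry and a second 3:1 operon. Canonical full
#' CF1/CF0 stoichiometries are shipped as an example table in
#' `inst/extdata/atp_synthase_canonical.tsv`.
#'
#' @return Tibble with columns `complex`, `gene_id`, `stoichiometry`,
#'   `operon_id`.
#' @export
default_plastid_complexes <- function() {
  tibble(
    complex = "atp_synthase",
    gene_id = c("atpA", "atpE", "atpI", "atpH", "atpB", "atpF"),
    stoichiometry = c(3L, 1L, 1L, 1L, 3L, 1L),
    operon_id = c("atp1", "atp1", "atp1", "atp1", "atp2", "atp2")
  )
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `riboheat_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `riboheat_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$plastid_complexes <- as.data.frame(x$plastid_complexes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pc <- if (is.null(x$plastid_complexes)) default_plastid_complexes() else
    as_tibble(lapply(x$plastid_complexes, unlist))
  args <- x[setdiff(names(x), "plastid_complexes")]
  args$n_per_class <- unlist(args$n_per_class)
  args$n_quadruplex_genes <- unlist(args$n_quadruplex_genes)
  do.call(sim_config, c(args, list(plastid_complexes = pc)))
}
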