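# CDS of n_codons codons: ATG start, TAA end, no internal in-frame stop
random_cds <- function(n_codons) {
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# one planted quadruplex motif of a tier: 4 G-runs, loops 1-7 nt from A/C/T
random_quadruplex <- function(tier) {
  k <- tier_runlen(tier)
  run <- strrep("G", k)
  loops <- vapply(sample(1:7, 3, replace = TRUE), function(l) {
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(run, loops[1], run, loops[2], run, loops[3], run)
}

splice_in <- function(seq, insert, at) {
  # 0-based insertion replacing nchar(insert) characters starting at `at`
  paste0(substr(seq, 1, at), insert, substr(seq, at + nchar(insert) + 1, nchar(seq)))
}

#' Generate a toy transcriptome with planted ground truth
#'
#' Builds one longest-transcript model per gene (5'UTR / CDS / 3'UTR) and
#' plants every feature the downstream analyses look for: differential
#' regulation classes, region-specific G-quadruplexes (with a
#' rejection-sampled quadruplex-free negative set in the same regions), an
#' A/U-rich upstream window for the low-structure (translationally
#' upregulated) group, one alternative-ORF gene whose coding sequence carries
#' an in-frame ATG at the planted change point followed by a charged peptide
#' and stop, a plastid operon set, and a heat-shock promoter element upstream
#' of the alternative-ORF gene.
#'
#' @param config A [sim_config()] object.
#' @return A list with `models` (tibble of transcript models) and `truth`
#'   (list of planted-feature tables).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "riboheat_config"))
  withr::with_seed(config$seed, generate_models(config))
}

generate_models <- function(config) {
  cls <- rep(names(config$n_per_class), config$n_per_class)
  n <- length(cls)
  gene_id <- sprintf("gene%04d", seq_len(n))
  utr5 <- sample(config$utr5_len[1]:config$utr5_len[2], n, replace = TRUE)
  cds <- 3L * sample((config$cds_len[1] %/% 3):(config$cds_len[2] %/% 3),
                     n, replace = TRUE)
  utr3 <- sample(config$utr3_len[1]:config$utr3_len[2], n, replace = TRUE)

  altorf_id <- NA_character_
  if (config$altorf_gene) {
    i_alt <- which(cls == "null")[1]
    if (is.na(i_alt)) abort("altorf_gene requires at least one null-class gene")
    altorf_id <- gene_id[i_alt]
    cds[i_alt] <- config$altorf_cds_len
    if (cds[i_alt] < 200L) abort("infeasible config: alt-ORF CDS shorter than 200 nt")
  }

  # quadruplex gene assignment: 5'UTR plantings go to translationally
  # upregulated genes first (they are the group the flanking metaprofile and
  # fold-change association interrogate), remaining regions fill from the
  # leftover pool
  pool <- c(which(cls == "rpf_only_up"), which(cls == "both_up"),
            which(cls == "null" & !gene_id %in% altorf_id))
  nq <- config$n_quadruplex_genes
  if (sum(nq) > length(pool)) abort("infeasible config: not enough genes for quadruplex planting")
  q_idx <- list(
    utr5 = pool[seq_len(nq[["utr5"]])],
    utr3 = pool[nq[["utr5"]] + seq_len(nq[["utr3"]])],
    cds  = pool[nq[["utr5"]] + nq[["utr3"]] + seq_len(nq[["cds"]])]
  )

  low_structure <- cls == "rpf_only_up"
  tier <- config$quadruplex_tier
  reject_regions <- names(nq)[nq > 0]

  quad_truth <- list()
  seqs <- character(n)
  for (i in seq_len(n)) {
    # CDS first: the 5'UTR negative-set check must also cover motifs
    # straddling the UTR/CDS junction
    cd <- random_cds(cds[i] %/% 3L)
    # --- 5'UTR ---
    make_utr5 <- function() {
      s <- random_dna(utr5[i], config$gc_background)
      if (low_structure[i]) {
        w <- min(config$structure_window, utr5[i])
        s <- paste0(substr(s, 1, utr5[i] - w), random_dna(w, config$gc_low_structure))
      }
      s
    }
    u5 <- make_utr5()
    if (i %in% q_idx$utr5) {
      motif <- random_quadruplex(tier)
      hi <- max(0L, utr5[i] - config$structure_window - nchar(motif) - 5L)
      at <- if (hi > 5L) sample(5:hi, 1) else 0L
      u5 <- splice_in(u5, motif, at)
      quad_truth[[length(quad_truth) + 1]] <- tibble(
        gene_id = gene_id[i], tier = tier, region = "utr5",
        start = at, end = at + nchar(motif))
    } else if ("utr5" %in% reject_regions) {
      # reject on matches *starting* in the UTR, including ones that run
      # into the first CDS bases
      cds_head <- substr(cd, 1, 40)
      u5 <- rejection_sample_region(make_utr5, cds_head, tier)
    }
    # --- 3'UTR ---
    make_utr3 <- function() random_dna(utr3[i], config$gc_background)
    u3 <- make_utr3()
    if (i %in% q_idx$utr3) {
      motif <- random_quadruplex(tier)
      hi <- utr3[i] - nchar(motif) - 5L
      at <- if (hi > 5L) sample(5:hi, 1) else 0L
      u3 <- splice_in(u3, motif, at)
      quad_truth[[length(quad_truth) + 1]] <- tibble(
        gene_id = gene_id[i], tier = tier, region = "utr3",
        start = utr5[i] + cds[i] + at, end = utr5[i] + cds[i] + at + nchar(motif))
    } else if ("utr3" %in% reject_regions) {
      u3 <- rejection_sample(make_utr3, tier)
    }
    # --- CDS ---
    if (i %in% q_idx$cds) {
      # overwrite two adjacent codon-aligned stretches with a motif, then
      # repair any stop codons introduced
      motif <- random_quadruplex(tier)
      at <- 3L * sample(2:((cds[i] - nchar(motif)) %/% 3 - 2), 1)
      cd <- splice_in(cd, motif, at)
      cd <- repair_stops(cd)
      quad_truth[[length(quad_truth) + 1]] <- tibble(
        gene_id = gene_id[i], tier = tier, region = "cds",
        start = utr5[i] + at, end = utr5[i] + at + nchar(motif))
    }
    seqs[i] <- paste0(u5, cd, u3)
  }

  models <- tibble(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".1"),
    sequence = seqs,
    utr5_start = 0L, utr5_end = utr5,
    cds_start = utr5, cds_end = utr5 + cds,
    utr3_start = utr5 + cds, utr3_end = utr5 + cds + utr3,
    length = utr5 + cds + utr3,
    compartment = "nuclear",
    operon_id = NA_character_
  )

  # plant the alternative ORF
  altorf_truth <- tibble()
  if (config$altorf_gene) {
    planted <- plant_alt_orf(models, altorf_id, config)
    models <- planted$models
    altorf_truth <- planted$truth
  }

  # plastid operon genes appended after the nuclear set
  pc <- config$plastid_complexes
  if (nrow(pc) > 0) {
    pn <- nrow(pc)
    # equal gene geometry across subunits so CDS ribosome density is
    # directly proportional to the planted per-gene output
    p_utr5 <- rep(60L, pn)
    p_cds <- rep(900L, pn)
    p_utr3 <- rep(60L, pn)
    p_seq <- vapply(seq_len(pn), function(j) {
      paste0(random_dna(p_utr5[j], config$gc_background),
             random_cds(p_cds[j] %/% 3L),
             random_dna(p_utr3[j], config$gc_background))
    }, character(1))
    plastid_models <- tibble(
      gene_id = pc$gene_id, transcript_id = paste0(pc$gene_id, ".1"),
      sequence = p_seq,
      utr5_start = 0L, utr5_end = p_utr5,
      cds_start = p_utr5, cds_end = p_utr5 + p_cds,
      utr3_start = p_utr5 + p_cds, utr3_end = p_utr5 + p_cds + p_utr3,
      length = p_utr5 + p_cds + p_utr3,
      compartment = "plastid", operon_id = pc$operon_id
    )
    models <- bind_rows(models, plastid_models)
    cls <- c(cls, rep("plastid", pn))
  }

  # promoter regions: 1 kb upstream per gene; plant the heat-shock element
  # AGAAnnTTCT at a recorded position upstream of the alt-ORF gene
  upstream <- vapply(seq_len(nrow(models)), function(i) {
    random_dna(1000L, config$gc_background)
  }, character(1))
  promoter_truth <- tibble()
  if (config$altorf_gene) {
    i_alt <- which(models$gene_id == altorf_id)
    at <- sample(100:800, 1)
    elem <- paste0("AGAA", random_dna(2L, 0.5), "TTCT")
    upstream[i_alt] <- splice_in(upstream[i_alt], elem, at)
    promoter_truth <- tibble(gene_id = altorf_id, pos = at, element = elem)
  }
  models$upstream <- upstream

  lfc <- config$lfc_effect
  class_tbl <- tibble(gene_id = models$gene_id, class = cls) %>%
    mutate(
      lfc_mrna = case_when(
        .data$class %in% c("both_up", "mrna_only_up") ~ lfc,
        .data$class %in% c("both_down", "mrna_only_down") ~ -lfc,
        TRUE ~ 0),
      lfc_te = case_when(
        .data$class == "rpf_only_up" ~ lfc,
        .data$class == "rpf_only_down" ~ -lfc,
        .data$class == "mrna_only_up" ~ -lfc,
        .data$class == "mrna_only_down" ~ lfc,
        TRUE ~ 0),
      lfc_rpf = .data$lfc_mrna + .data$lfc_te
    )

  truth <- list(
    classes = class_tbl,
    quadruplexes = if (length(quad_truth)) bind_rows(quad_truth) else
      tibble(gene_id = character(), tier = character(), region = character(),
             start = integer(), end = integer()),
    quadruplex_negative = tibble(
      region = rep(reject_regions, each = 0)),  # filled below
    altorf = altorf_truth,
    promoter = promoter_truth,
    spikeins = tibble(
      spikein_id = sprintf("spike%02d", seq_along(config$spikein_concentrations)),
      concentration = config$spikein_concentrations,
      below_floor = config$spikein_concentrations < config$spikein_floor),
    spikein_floor = config$spikein_floor,
    complexes = pc,
    config = config
  )
  # negative set: genes eligible for a planted region but left motif-free
  neg <- purrr::map(reject_regions, function(r) {
    tibble(region = r,
           gene_id = setdiff(models$gene_id[cls != "plastid"],
                             c(truth$quadruplexes$gene_id[truth$quadruplexes$region == r],
                               altorf_id)))
  })
  truth$quadruplex_negative <- if (length(neg)) bind_rows(neg) else truth$quadruplex_negative

  list(models = models, truth = truth)
}

# resample seq_fun() until the tier has no match, cap 10,000 attempts
rejection_sample <- function(seq_fun, tier, max_attempts = 10000L) {
  for (a in seq_len(max_attempts)) {
    s <- seq_fun()
    if (nrow(scan_sequence(s, tier)) == 0) return(s)
  }
  abort(sprintf("rejection sampling failed after %d attempts (tier %s)",
                max_attempts, tier))
}

# like rejection_sample(), but also rejects matches that start inside the
# sampled region and extend into the fixed downstream context
rejection_sample_region <- function(seq_fun, downstream, tier,
                                    max_attempts = 10000L) {
  for (a in seq_len(max_attempts)) {
    s <- seq_fun()
    h <- scan_sequence(paste0(s, downstream), tier)
    if (!any(h$start < nchar(s))) return(s)
  }
  abort(sprintf("rejection sampling failed after %d attempts (tier %s)",
                max_attempts, tier))
}

repair_stops <- function(cds) {
  n_cod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  bad <- which(codons %in% c("TAA", "TAG", "TGA"))
  bad <- bad[bad != n_cod]
  if (length(bad)) codons[bad] <- sample(SENSE_CODONS, length(bad), replace = TRUE)
  codons[n_cod] <- "TAA"
  paste(codons, collapse = "")
}

plant_alt_orf <- function(models, altorf_id, config) {
  i <- which(models$gene_id == altorf_id)
  m <- models[i, ]
  cp <- config$altorf_changepoint            # CDS coordinate, 0-based
  alt_start <- 3L * as.integer(ceiling(cp / 3))
  pep_len <- config$altorf_peptide_len
  n_kr <- round(config$altorf_kr_frac * pep_len)
  body <- sample(setdiff(SENSE_CODONS, c(KR_CODONS, "ATG")), pep_len - 1L,
                 replace = TRUE)
  kr_at <- sample(pep_len - 1L, min(n_kr, pep_len - 1L))
  body[kr_at] <- sample(KR_CODONS, length(kr_at), replace = TRUE)
  orf <- paste0("ATG", paste(body, collapse = ""), "TAA")

  cds_seq <- substr(m$sequence, m$cds_start + 1, m$cds_end)
  # clear any in-frame ATG well upstream of the planted start so the first
  # in-frame ATG found near the (estimated) change point is the planted one
  lo <- max(0L, cp - 60L)
  n_cod <- nchar(cds_seq) %/% 3L
  codons <- substring(cds_seq, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  pre <- which((3 * (seq_len(n_cod) - 1)) >= lo &
                 (3 * (seq_len(n_cod) - 1)) < alt_start)
  codons[pre][codons[pre] == "ATG"] <-
    sample(setdiff(SENSE_CODONS, "ATG"), sum(codons[pre] == "ATG"), replace = TRUE)
  cds_seq <- paste(codons, collapse = "")
  cds_seq <- splice_in(cds_seq, orf, alt_start)
  cds_seq <- repair_stops_outside(cds_seq, alt_start, alt_start + nchar(orf))

  models$sequence[i] <- paste0(
    substr(m$sequence, 1, m$cds_start), cds_seq,
    substr(m$sequence, m$cds_end + 1, m$length))

  pep <- translate_to_stop(substr(cds_seq, alt_start + 1, nchar(cds_seq)))
  truth <- tibble(
    gene_id = altorf_id,
    changepoint_cds = cp,
    changepoint_tx = m$cds_start + cp,
    alt_start_cds = alt_start,
    alt_start_tx = m$cds_start + alt_start,
    peptide = pep$peptide,
    peptide_len = nchar(pep$peptide),
    frac_positive = mean(strsplit(pep$peptide, "")[[1]] %in% c("K", "R")),
    step_ratio = config$altorf_step
  )
  list(models = models, truth = truth)
}

# keep codons outside [from, to) stop-free (final stop preserved)
repair_stops_outside <- function(cds, from, to) {
  n_cod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  pos0 <- 3 * (seq_len(n_cod) - 1)
  bad <- which(codons %in% c("TAA", "TAG", "TGA") &
                 (pos0 < from | pos0 >= to) & seq_len(n_cod) != n_cod)
  if (length(bad)) codons[bad] <- sample(SENSE_CODONS, length(bad), replace = TRUE)
  codons[n_cod] <- "TAA"
  paste(codons, collapse = "")
}

#' Simulate paired RNA-Seq / Ribo-Seq read sets
#'
#' Draws gene totals from a negative binomial (variance `mu + alpha mu^2`)
#' with condition-specific planted fold changes (mRNA fold change on the RNA
#' assay; RPF fold change = mRNA x translational-efficiency fold change),
#' then places read 5' ends multinomially along each transcript: uniform
#' except for (a) a step increase downstream of the planted change point in
#' the alt-ORF gene's stress RPF libraries, (b) an elevation over planted UTR
#' quadruplex windows in the stress RPF libraries, and (c) plastid RPF output
#' proportional to declared subunit stoichiometry (scaled down uniformly
#' under heat, with one subunit disproportionately halved). Spike-ins are
#' added to RNA libraries only, at the configured concentration ladder with
#' dropout below the planted floor.
#'
#' @param sim Result of [simulate_transcriptome()].
#' @param config The [sim_config()] used to generate `sim`.
#' @param seed Seed for the read-level randomness; defaults to
#'   `config$seed + 1`.
#' @return A list with `reads` (tibble: sample_id, assay, condition,
#'   replicate, transcript_id, pos, length), `spikeins` (tibble of spike-in
#'   counts per RNA sample with known concentrations) and `samples` (per
#'   sample metadata including the drawn library-size factor).
#' @export
simulate_reads <- function(sim, config, seed = NULL) {
  stopifnot(inherits(config, "riboheat_config"))
  seed <- seed %||% (config$seed + 1L)
  withr::with_seed(seed, draw_reads(sim, config))
}

draw_reads <- function(sim, config) {
  models <- sim$models
  truth <- sim$truth
  samples <- tidyr::expand_grid(
    assay = c("rna", "rpf"), condition = c("control", "heat"),
    replicate = 1:2) %>%
    mutate(sample_id = paste(.data$assay, .data$condition, .data$replicate,
                             sep = "_"),
           lib_factor = runif(dplyr::n(), config$lib_jitter[1], config$lib_jitter[2]))

  cls <- truth$classes
  pc <- truth$complexes
  base <- models %>%
    select("gene_id", "transcript_id", "length", "cds_start", "cds_end",
           "compartment") %>%
    left_join(cls, by = "gene_id")

  # per gene x sample expected totals
  grid <- tidyr::expand_grid(gene_id = base$gene_id,
                             sample_id = samples$sample_id) %>%
    left_join(base, by = "gene_id") %>%
    left_join(samples, by = "sample_id") %>%
    mutate(
      fc = if_else(.data$condition == "heat",
                   if_else(.data$assay == "rna", 2^.data$lfc_mrna, 2^.data$lfc_rpf),
                   1),
      stoich_w = 1
    )
  if (nrow(pc) > 0) {
    grid <- grid %>%
      left_join(pc %>% select("gene_id", "stoichiometry"), by = "gene_id") %>%
      mutate(
        stoich_w = if_else(.data$compartment == "plastid" & .data$assay == "rpf",
                           as.numeric(.data$stoichiometry), .data$stoich_w),
        fc = if_else(.data$compartment == "plastid" & .data$assay == "rpf" &
                       .data$condition == "heat",
                     .data$fc * config$plastid_heat_scale, .data$fc),
        fc = if_else(.data$compartment == "plastid" & .data$assay == "rpf" &
                       .data$condition == "heat" &
                       .data$gene_id %in% config$plastid_disprop_gene,
                     .data$fc * config$plastid_disprop_factor, .data$fc)
      ) %>%
      select(-"stoichiometry")
  }
  grid <- grid %>%
    mutate(mu = config$depth * .data$lib_factor * .data$fc * .data$stoich_w,
           total = rnbinom(dplyr::n(), mu = .data$mu, size = 1 / config$dispersion))

  max_len <- config$read_len[2]
  q5 <- truth$quadruplexes %>% filter(.data$region %in% c("utr5", "utr3"))
  alt <- truth$altorf
  boost <- config$quadruplex_boost

  reads <- purrr::pmap(
    list(grid$transcript_id, grid$gene_id, grid$length, grid$total,
         grid$assay, grid$condition, grid$cds_start),
    function(tx, g, L, tot, assay, condition, cds_start) {
      if (tot == 0 || L <= max_len) {
        return(tibble(transcript_id = character(), pos = integer(),
                      length = integer()))
      }
      npos <- L - max_len
      stress_rpf <- assay == "rpf" && condition == "heat"
      w <- NULL
      if (stress_rpf) {
        qh <- q5[q5$gene_id == g, ]
        has_step <- nrow(alt) > 0 && g %in% alt$gene_id
        if (nrow(qh) > 0 || has_step) {
          w <- rep(1, npos)
          if (nrow(qh) > 0) {
            for (r in seq_len(nrow(qh))) {
              lo <- max(1L, qh$start[r] - 30L + 1L)
              hi <- min(npos, qh$end[r])
              w[lo:hi] <- w[lo:hi] * boost
            }
          }
          if (has_step) {
            # boost reads whose midpoint falls past the change point, so the
            # coverage step sits at the planted position rather than half a
            # read length downstream
            cp_tx <- alt$changepoint_tx[alt$gene_id == g][1] -
              mean(config$read_len) %/% 2
            if (cp_tx + 1 <= npos) {
              w[max(1, cp_tx + 1):npos] <-
                w[max(1, cp_tx + 1):npos] * config$altorf_step
            }
          }
        }
      }
      pos <- if (is.null(w)) sample.int(npos, tot, replace = TRUE) - 1L else
        sample.int(npos, tot, replace = TRUE, prob = w) - 1L
      tibble(transcript_id = tx, pos = pos,
             length = sample(config$read_len[1]:config$read_len[2], tot,
                             replace = TRUE))
    })
  reads <- bind_cols(
    grid %>% select("sample_id", "assay", "condition", "replicate") %>%
      mutate(.n = vapply(reads, nrow, integer(1))) %>%
      tidyr::uncount(.data$.n),
    bind_rows(reads))

  # spike-ins: RNA libraries only, dropout below the planted floor
  spike <- truth$spikeins
  rna_samples <- samples %>% filter(.data$assay == "rna")
  spikeins <- tidyr::expand_grid(spikein_id = spike$spikein_id,
                                 sample_id = rna_samples$sample_id) %>%
    left_join(spike, by = "spikein_id") %>%
    left_join(rna_samples %>% select("sample_id", "condition", "replicate",
                                     "lib_factor"),
              by = "sample_id") %>%
    mutate(
      mu = config$spikein_scale * .data$lib_factor *
        if_else(.data$concentration >= config$spikein_floor,
                .data$concentration,
                .data$concentration^2 / config$spikein_floor),
      count = rnbinom(dplyr::n(), mu = .data$mu, size = 1 / config$dispersion),
      length = config$spikein_length
    ) %>%
    select("spikein_id", "sample_id", "condition", "replicate",
           "concentration", "count", "length")

  list(reads = as_tibble(reads), spikeins = spikeins,
       samples = samples %>% select("sample_id", "assay", "condition",
                                    "replicate", "lib_factor"))
}

#' Run the full simulation in one call
#'
#' @param config A [sim_config()]; defaults to `sim_config()`.
#' @return A list with `models`, `truth`, `reads`, `spikeins`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  sim <- simulate_transcriptome(config)
  rd <- simulate_reads(sim, config)
  c(sim, rd)
}
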