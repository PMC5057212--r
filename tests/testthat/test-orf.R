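test_that("a lone asymmetric gene is flagged by the robust z-screen", {
  sym <- tibble(gene_id = sprintf("g%02d", 1:25), assay = "rpf",
                condition = "heat",
                first_half = c(rep(50L, 24), 5L),
                second_half = c(rep(50L, 24), 95L)) %>%
    mutate(frac_first = first_half / (first_half + second_half))
  # add binomial wobble so the MAD is nonzero
  set.seed(51)
  sym$frac_first[1:24] <- 0.5 + rnorm(24, 0, 0.02)
  out <- asymmetry_outliers(sym)
  expect_true(out$outlier[25])
  expect_equal(out$direction[25], "second_half")
  expect_equal(sum(out$outlier), 1)
})

test_that("zero-MAD cohorts fall back to the SD and then to no outliers", {
  sym <- tibble(gene_id = paste0("g", 1:20), assay = "rpf",
                condition = "heat", first_half = 50L, second_half = 50L,
                frac_first = 0.5)
  out <- asymmetry_outliers(sym)
  expect_false(any(out$outlier))
})

test_that("the change-point estimator localizes a planted step", {
  set.seed(52)
  hits <- purrr::map_lgl(1:50, function(i) {
    depth <- c(rpois(2195, 2), rpois(605, 20))
    cp <- find_changepoint(depth)
    abs(cp$changepoint - 2195) <= 15 && !cp$no_step
  })
  expect_gte(mean(hits), 0.9)
  # constant coverage is a no-step
  flat <- find_changepoint(rep(5, 500))
  expect_true(flat$no_step)
  # a step close to the edge is still localized
  edge <- find_changepoint(c(rpois(12, 2), rpois(2788, 20)))
  expect_lte(abs(edge$changepoint - 12), 15)
})

test_that("alternative ORFs are called from the planted sequence", {
  cfg <- tiny_config(seed = 53)
  sim <- simulate_transcriptome(cfg)
  alt <- sim$truth$altorf
  m <- sim$models %>% filter(gene_id == alt$gene_id)
  call <- call_alt_orf(m, alt$changepoint_cds)
  expect_equal(call$alt_start, alt$alt_start_cds)
  expect_equal(call$peptide_len, alt$peptide_len)
  expect_equal(call$status, "ok")
  # the reported peptide equals an independent re-translation
  cds <- substr(m$sequence, m$cds_start + 1, m$cds_end)
  sub <- substr(cds, call$alt_start + 1, nchar(cds))
  n_cod <- nchar(sub) %/% 3
  cods <- substring(sub, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  aa <- vapply(cods, function(cd)
    as.character(Biostrings::GENETIC_CODE[[cd]]), character(1))
  stop_at <- which(aa == "*")[1]
  expect_equal(call$peptide, paste(aa[seq_len(stop_at - 1)], collapse = ""))
  expect_equal(call$frac_positive,
               mean(aa[seq_len(stop_at - 1)] %in% c("K", "R")))
})

test_that("degenerate ORF calls are handled without error", {
  m <- toy_model(utr5 = 0L, cds = 240L, utr3 = 0L,
                 sequence = paste0("ATGTAA", strrep("GCA", 77), "TGA"))
  # immediate stop after the start codon: peptide of length 1 (Met)
  call <- call_alt_orf(m, 0L)
  expect_equal(call$alt_start, 0L)
  expect_equal(call$peptide_len, 1L)
  # no ATG anywhere in the window -> rejected with reason
  m2 <- toy_model(utr5 = 0L, cds = 240L, utr3 = 0L,
                  sequence = paste0(strrep("GCA", 79), "TAA"))
  call2 <- call_alt_orf(m2, 30L)
  expect_true(is.na(call2$alt_start))
  expect_match(call2$status, "no in-frame ATG")
  expect_error(call_alt_orf(m2, 999L), "outside")
})

test_that("promoter element scanning is strand-symmetric and exact", {
  set.seed(54)
  bg <- random_seq(1000, gc = 0.5)
  elem <- "AGAACGTTCT"
  planted <- paste0(substr(bg, 1, 100), elem, substr(bg, 111, 1000))
  hits <- promoter_element_scan(planted)
  expect_true(100 %in% hits$start[hits$strand == "+"])
  # the consensus is its own reverse complement, so the minus strand
  # reports the same locus
  expect_true(100 %in% hits$start[hits$strand == "-"])
  # a plus-only element: plant the reverse complement of a non-palindromic
  # variant and expect it on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AGAAGGTTCT")))
  planted2 <- paste0(substr(bg, 1, 200), rc, substr(bg, 211, 1000))
  hits2 <- promoter_element_scan(planted2)
  expect_true(200 %in% hits2$start[hits2$strand == "-"])
})

test_that("promoter scanning equals a brute-force comparison", {
  set.seed(55)
  consensus <- strsplit("AGAANNTTCT", "")[[1]]
  brute <- function(seq) {
    s <- strsplit(seq, "")[[1]]
    rcs <- rev(chartr("ACGT", "TGCA", s))
    hit <- function(v, p) all(v[p:(p + 9)] == consensus |
                                consensus == "N")
    fwd <- which(vapply(1:(length(s) - 9), hit, logical(1), v = s)) - 1L
    rev_ <- which(vapply(1:(length(s) - 9), hit, logical(1), v = rcs)) - 1L
    # minus-strand positions back to forward coordinates
    rev_fwd <- length(s) - rev_ - 10L
    list(fwd = fwd, rev = sort(rev_fwd))
  }
  for (i in 1:20) {
    sq <- random_seq(500, gc = 0.55)
    got <- promoter_element_scan(sq)
    want <- brute(sq)
    expect_equal(sort(got$start[got$strand == "+"]), want$fwd)
    expect_equal(sort(got$start[got$strand == "-"]), want$rev)
  }
})

test_that("UTR RPF gain selection recovers planted gains and stays specific", {
  cfg <- tiny_config(seed = 56)
  sim <- simulate_experiment(cfg)
  q5 <- sim$truth$quadruplexes %>% filter(region == "utr5")
  universe <- sim$truth$classes %>%
    filter(class %in% c("rpf_only_up", "both_up", "null")) %>% pull(gene_id)
  sel <- select_utr_rpf_gain_genes(sim$reads, sim$models, universe, "utr5")
  # the stress RPF elevation sits on the planted 5'UTR quadruplex genes
  expect_gt(mean(q5$gene_id %in% sel$gene_id), 0.6)
  # expression-neutral genes do not gain UTR footprints
  neutral <- sim$truth$classes %>% filter(class == "null") %>% pull(gene_id)
  expect_lt(mean(intersect(universe, neutral) %in% sel$gene_id), 0.1)
  # selections are monotone in the fold-change threshold
  sel_lo <- select_utr_rpf_gain_genes(sim$reads, sim$models, universe,
                                      "utr5", min_fc = 1.2)
  expect_true(all(sel$gene_id %in% sel_lo$gene_id))
  # no reads at all: empty selection
  sel0 <- select_utr_rpf_gain_genes(sim$reads[0, ], sim$models, universe,
                                    "utr5")
  expect_equal(nrow(sel0), 0)
  # FASTA export writes the selected UTRs
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "utr.fa")
  select_utr_rpf_gain_genes(sim$reads, sim$models, universe, "utr5",
                            fasta_out = fa)
  expect_true(file.exists(fa))
  exported <- Biostrings::readDNAStringSet(fa)
  expect_gt(length(exported), 0)
})
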