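scan_one <- function(seq, tier, mode = "anchored") {
  m <- toy_model(utr5 = 0L, cds = 0L, utr3 = 0L)
  m$sequence <- seq
  m$length <- nchar(seq)
  m$utr3_end <- m$length
  m$cds_start <- m$cds_end <- m$utr5_end <- m$utr3_start <- 0L
  scan_quadruplexes(m, tiers = tier, mode = mode)
}

test_that("the scanner matches the grammar on canonical strings", {
  h <- scan_one("GGAGGAGGAGG", "G2")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 11L)
  # loop longer than 7 breaks the grammar
  h2 <- scan_one("GGAAAAAAAAGGAGGAGG", "G2")
  expect_equal(nrow(h2), 0)
  # G3 string yields one G3 hit and at least one G2 hit (tiers independent)
  s3 <- "GGGAGGGAGGGAGGG"
  expect_equal(nrow(scan_one(s3, "G3")), 1)
  expect_gte(nrow(scan_one(s3, "G2")), 1)
})

test_that("planted motifs with short loops show tier containment", {
  set.seed(41)
  for (i in 1:20) {
    loops <- replicate(3, paste(sample(c("A", "C", "T"),
                                       sample(1:5, 1), replace = TRUE),
                                collapse = ""))
    motif <- paste0("GGGG", loops[1], "GGGG", loops[2], "GGGG", loops[3],
                    "GGGG")
    seq <- paste0(random_seq(20, gc = 0.2), motif, random_seq(20, gc = 0.2))
    h4 <- scan_one(seq, "G4")
    expect_gte(nrow(h4), 1)
    a <- h4$start[1]
    expect_true(a %in% scan_one(seq, "G3")$start)
    expect_true(a %in% scan_one(seq, "G2")$start)
  }
})

test_that("scanner hits equal the exhaustive grammar enumeration", {
  set.seed(42)
  for (tier in c("G2", "G3", "G4")) {
    k <- c(G2 = 2L, G3 = 3L, G4 = 4L)[[tier]]
    for (i in 1:25) {
      sq <- random_seq(2000, gc = 0.5)
      got <- scan_one(sq, tier)
      want <- oracle_quadruplex_starts(sq, k)
      expect_equal(got$start, sort(want),
                   info = sprintf("%s rep %d", tier, i))
      # every reported match parses under the grammar
      for (ms in got$match) {
        expect_true(oracle_validate_match(ms, k))
      }
    }
  }
})

test_that("regions are assigned by the hit start and both modes work", {
  cfg <- tiny_config(seed = 43)
  sim <- simulate_transcriptome(cfg)
  hits <- scan_quadruplexes(sim$models, tiers = "G2")
  m <- sim$models %>% select(gene_id, cds_start, cds_end)
  j <- hits %>% left_join(m, by = "gene_id")
  expect_true(all(j$region[j$start < j$cds_start] == "utr5"))
  expect_true(all(j$region[j$start >= j$cds_end] == "utr3"))
  all_mode <- scan_quadruplexes(sim$models, tiers = "G2", mode = "all")
  # anchored hits are a subset of all-mode hits
  expect_true(all(paste(hits$gene_id, hits$start) %in%
                    paste(all_mode$gene_id, all_mode$start)))
  expect_gte(nrow(all_mode), nrow(hits))
})

test_that("uniform coverage gives a flat ratio profile at the rpm scale", {
  set.seed(44)
  m <- toy_model(utr5 = 200L, cds = 300L, utr3 = 100L)
  hits <- tibble(gene_id = "g1", tier = "G2", region = "utr5",
                 start = 100L, end = 111L, match = "GGAGGAGGAGG")
  # 1-nt reads tiling every position: rpf depth 10, rna depth 5
  mk <- function(assay, cond, times) {
    toy_reads("g1.1", rep(0:(m$length - 1), times), 1,
              sample_id = paste(assay, cond, 1, sep = "_"),
              assay = assay, condition = cond)
  }
  reads <- bind_rows(mk("rpf", "control", 10), mk("rna", "control", 5),
                     mk("rpf", "heat", 10), mk("rna", "heat", 5))
  fl <- flank_metaprofile(hits, reads, m)
  prof <- fl$profile %>% filter(!is.na(mean_control))
  total_rpf <- 10 * m$length
  expected <- (10 * 1e6 / total_rpf) / 5
  expect_true(all(abs(prof$mean_control - expected) < 1e-9))
  # identical conditions: all paired differences zero -> p = 1
  expect_equal(fl$test$p, 1)
})

test_that("flank positions outside the transcript are missing", {
  m <- toy_model(utr5 = 50L, cds = 300L, utr3 = 50L)
  hits <- tibble(gene_id = "g1", tier = "G2", region = "utr5",
                 start = 30L, end = 50L, match = "x")
  reads <- toy_reads("g1.1", rep(0, 40), 30, sample_id = "rpf_control_1",
                     assay = "rpf", condition = "control")
  fl <- flank_metaprofile(hits, bind_rows(
    reads, reads %>% mutate(sample_id = "rpf_heat_1", condition = "heat"),
    reads %>% mutate(sample_id = "rna_control_1", assay = "rna"),
    reads %>% mutate(sample_id = "rna_heat_1", assay = "rna",
                     condition = "heat")), m)
  expect_true(all(is.na(fl$profile$mean_control[fl$profile$position < -30])))
  expect_equal(nrow(fl$profile), 450)
})

test_that("duplicating a gene's hits does not change the metaprofile", {
  cfg <- tiny_config(seed = 45, n_genes = 30, depth = 200,
                     n_per_class = c(rpf_only_up = 10L, null = NA_integer_))
  sim <- simulate_experiment(cfg)
  hits <- scan_quadruplexes(sim$models, tiers = "G2") %>%
    filter(region == "utr5")
  fl1 <- flank_metaprofile(hits, sim$reads, sim$models)
  fl2 <- flank_metaprofile(bind_rows(hits, hits), sim$reads, sim$models)
  expect_equal(fl1$profile$mean_control, fl2$profile$mean_control)
  expect_equal(fl1$profile$mean_heat, fl2$profile$mean_heat)
})

test_that("an empty hit class yields an empty profile and no test", {
  fl <- flank_metaprofile(tibble(), tibble(), tibble())
  expect_equal(fl$n_genes, 0)
  expect_true(is.na(fl$test$statistic))
})

test_that("fold-change association splits quadruplex genes by RPF class", {
  hits <- tibble(gene_id = c("g1", "g2", "g3"), tier = "G2",
                 region = "utr5", start = 0L, end = 11L, match = "x")
  res <- tibble(gene_id = paste0("g", 1:4),
                log2fc_mrna = 0, p_mrna = 1, padj_mrna = 1,
                log2fc_rpf = c(2, 1.5, 0, 0), p_rpf = 1, padj_rpf = 1,
                class = c("rpf_only_up", "both_up", "unchanged", "unchanged"))
  assoc <- quadruplex_fold_change_association(hits, res)
  expect_equal(assoc$n_up, 2)
  expect_equal(assoc$n_0_down, 1)
  expect_true(all(assoc$groups$group[assoc$groups$gene_id %in%
                                       c("g1", "g2")] == "rpf_up"))
  # no quadruplex genes: both groups empty, test skipped
  empty <- quadruplex_fold_change_association(hits[0, ], res)
  expect_equal(empty$n_up + empty$n_0_down, 0)
  expect_true(is.na(empty$p))
})

test_that("3'UTR half-read check sees no shift in a stability-neutral sim", {
  cfg <- tiny_config(seed = 47)
  sim <- simulate_experiment(cfg)
  hits <- scan_quadruplexes(sim$models, tiers = "G2")
  chk <- utr3_half_reads_check(hits, sim$reads, sim$models)
  expect_gt(chk$n, 3)
  expect_gt(chk$p, 0.05)
})
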