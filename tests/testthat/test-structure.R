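test_that("folding energy behaves on canonical cases", {
  expect_equal(fold_mfe("AAAAA"), 0)
  expect_equal(fold_mfe(strrep("A", 39)), 0)
  # a perfect GC hairpin: 4 GC pairs = -12
  expect_equal(fold_mfe("GGGGAAACCCC"), -12)
  # T is read as U
  expect_equal(fold_mfe("GGGGAAACCCC"), fold_mfe("GGGGAAACCCC"))
  expect_equal(fold_mfe("GGAAATT"), fold_mfe("GGAAAUU"))
  # GC-rich folds lower than AU-rich of the same layout
  expect_lt(fold_mfe("GCGCGCAAAGCGCGC"), fold_mfe("AUAUAUAAAAUAUAU"))
  expect_error(fold_mfe("ACGX"), "invalid")
})

test_that("the dynamic program equals exhaustive structure enumeration", {
  set.seed(11)
  seqs <- c("GCGCAAAGCGC", "GGGAAAACCC",
            replicate(120, random_seq(sample(4:11, 1))))
  for (sq in seqs) {
    expect_equal(fold_mfe(sq), oracle_fold_enum(sq), info = sq)
  }
})

test_that("the dynamic program matches an independent DP up to length 14", {
  set.seed(12)
  seqs <- replicate(200, random_seq(sample(4:14, 1)))
  expect_equal(fold_mfe(seqs),
               vapply(seqs, oracle_fold_dp, numeric(1), USE.NAMES = FALSE))
})

test_that("reverse complement of a palindromic hairpin scores the same", {
  sq <- "GGGCAAAGCCC"
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sq), "")[[1]]), collapse = "")
  expect_equal(fold_mfe(sq), fold_mfe(rc))
})

test_that("window profiles honour the span and transcript bounds", {
  m <- toy_model(utr5 = 50L, cds = 90L, utr3 = 20L,
                 sequence = strrep("A", 160))
  pr <- mfe_profile(m, span = c(-60L, 60L))
  # all-A: defined positions have energy 0
  expect_true(all(pr$energy == 0))
  # windows need 19 nt on each side: centres 19 .. 140 exist;
  # centre = 50 + rel -> rel in [-31, 90] intersect [-60, 60]
  expect_equal(min(pr$position), -31L)
  expect_equal(max(pr$position), 60L)
  # too-short transcript -> empty profile
  short <- toy_model(utr5 = 10L, cds = 9L, utr3 = 10L,
                     sequence = strrep("A", 29))
  expect_equal(nrow(mfe_profile(short)), 0)
})

test_that("profiles depend only on window content (translation invariance)", {
  set.seed(13)
  core <- random_seq(120)
  m1 <- toy_model(utr5 = 40L, cds = 60L, utr3 = 20L,
                  sequence = core)
  # same sequence content shifted 30 nt downstream in a longer transcript
  pr1 <- mfe_profile(m1, span = c(-20L, 20L))
  m2 <- toy_model(gene_id = "g2", utr5 = 70L, cds = 50L, utr3 = 30L,
                  sequence = paste0(random_seq(30), core))
  pr2 <- mfe_profile(m2, span = c(-20L, 20L))
  # absolute centre in m1 = 40 + rel; in m2 = 70 + rel, over the same
  # sequence content shifted by 30
  j <- inner_join(pr1, pr2, by = "position")
  expect_equal(j$energy.x, j$energy.y)
})

test_that("metaprofile of duplicated genes equals the single-gene profile", {
  set.seed(14)
  m <- toy_model(sequence = random_seq(150))
  pr <- mfe_profile(m, span = c(-20L, 20L))
  pr3 <- bind_rows(pr, pr %>% mutate(gene_id = "g2"),
                   pr %>% mutate(gene_id = "g3"))
  groups <- tibble(gene_id = c("g1", "g2", "g3"), group = "all")
  gm <- group_metaprofile(pr3, groups, region = c(-20L, 0L))
  expect_equal(gm$profile$mean, pr$energy)
  expect_equal(gm$profile$n, rep(3L, nrow(pr)))
  # single-gene group: sd is 0
  g1 <- group_metaprofile(pr, tibble(gene_id = "g1", group = "solo"),
                          region = c(-20L, 0L))
  expect_true(all(g1$profile$sd == 0))
})

test_that("identical groups show no upstream-region shift", {
  set.seed(15)
  prof <- purrr::map(1:10, function(i) {
    tibble(gene_id = paste0("g", i), position = -30:0,
           energy = rnorm(31, -5))
  }) %>% bind_rows()
  groups <- tibble(gene_id = paste0("g", 1:10),
                   group = rep(c("a", "b"), 5))
  # copy group a's energies into group b so distributions are identical
  ab <- prof %>%
    left_join(groups, by = "gene_id")
  fixed <- ab %>% group_by(position) %>%
    mutate(energy = energy[match(group, group)][1]) %>% ungroup()
  gm <- group_metaprofile(prof, groups, region = c(-30L, 0L))
  expect_true(gm$tests$p > 0.05)
})

test_that("a planted A/U-rich upstream group has higher (less negative) energy", {
  cfg <- tiny_config(seed = 33, n_genes = 40,
                     n_per_class = c(rpf_only_up = 12L, null = NA_integer_),
                     n_quadruplex_genes = c(utr5 = 0L, cds = 0L, utr3 = 0L))
  sim <- simulate_transcriptome(cfg)
  pr <- mfe_profile(sim$models %>% filter(compartment == "nuclear"),
                    span = c(-110L, 10L))
  grp <- sim$truth$classes %>%
    filter(class %in% c("rpf_only_up", "null")) %>%
    transmute(gene_id,
              group = ifelse(class == "rpf_only_up", "up", "background"))
  gm <- group_metaprofile(pr, grp, region = c(-100L, 0L))
  mu <- gm$region_energy %>% group_by(group) %>%
    summarise(m = mean(mean_energy), .groups = "drop")
  expect_gt(mu$m[mu$group == "up"], mu$m[mu$group == "background"])
  expect_lt(gm$tests$p, 0.01)
})

test_that("small groups skip the test with a warning", {
  prof <- tibble(gene_id = rep(c("g1", "g2", "g3", "g4"), each = 3),
                 position = rep(-2:0, 4), energy = rnorm(12))
  groups <- tibble(gene_id = paste0("g", 1:4),
                   group = c("a", "a", "b", "b"))
  expect_warning(gm <- group_metaprofile(prof, groups, region = c(-2L, 1L)),
                 "skipped")
  expect_true(is.na(gm$tests$p))
})

test_that("a custom folding backend can be substituted", {
  m <- toy_model(sequence = random_seq(150))
  pr <- mfe_profile(m, span = c(-5L, 5L), backend = function(x) -nchar(x))
  expect_true(all(pr$energy == -39))
  expect_equal(attr(pr, "backend"), "custom")
})
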