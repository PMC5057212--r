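test_that("production follows the rpkm unit arithmetic", {
  counts <- bind_rows(
    counts_from_matrix(matrix(1000L, 1, 4,
                              dimnames = list("g1", paste0("s", 1:4))),
                       assay = "rpf", region_len = 1000L),
    counts_from_matrix(matrix(500L, 1, 4,
                              dimnames = list("g1", paste0("s", 5:8))),
                       assay = "rna", region_len = 1000L))
  counts$total <- 1e6
  m <- toy_model(cds = 999L, utr5 = 0L, utr3 = 1L)
  prod <- protein_production(counts, m)
  expect_equal(unique(prod$rpf_rpkm), 1000)
  expect_equal(unique(prod$mrna_rpkm), 500)
  expect_equal(unique(prod$production), 1000)
  # te mode: headline switches, value = rpf / (mrna + 0.5)
  te <- protein_production(counts, m, mode = "te")
  expect_equal(unique(te$production), 1000 / 500.5)
})

test_that("translational efficiency is invariant to depth scaling", {
  set.seed(61)
  m <- toy_model(cds = 900L, utr5 = 50L, utr3 = 50L)
  base <- bind_rows(
    counts_from_matrix(matrix(800L, 1, 4,
                              dimnames = list("g1", paste0("s", 1:4))),
                       assay = "rpf", region_len = 900L),
    counts_from_matrix(matrix(400L, 1, 4,
                              dimnames = list("g1", paste0("s", 5:8))),
                       assay = "rna", region_len = 900L))
  doubled <- base %>% mutate(count = count * 2L, total = total * 2)
  te1 <- protein_production(base, m, mode = "te")
  te2 <- protein_production(doubled, m, mode = "te")
  expect_equal(te1$rpf_rpkm, te2$rpf_rpkm)
  expect_lt(max(abs(te1$te - te2$te)), 0.01 * max(te1$te))
})

test_that("stoichiometry audit reproduces exact proportionality", {
  prod <- tibble(gene_id = c("a", "b", "c", "d"),
                 condition = "control",
                 rpf_rpkm = c(300, 100, 100, 100),
                 mrna_rpkm = 100, te = 1, unstable = FALSE,
                 production = c(300, 100, 100, 100))
  cx <- tibble(complex = "cplx", gene_id = c("a", "b", "c", "d"),
               stoichiometry = c(3L, 1L, 1L, 1L), operon_id = "op1")
  audit <- stoichiometry_audit(prod, cx)
  expect_equal(audit$complexes$spearman, 1)
  expect_equal(sort(audit$subunits$obs_ratio), sort(c(3, 1, 1, 1)))
  expect_equal(audit$subunits$obs_ratio, audit$subunits$exp_ratio)
  # anti-ordered production
  prod2 <- prod %>% mutate(production = c(50, 100, 150, 200)[c(1, 2, 3, 4)])
  cx2 <- tibble(complex = "cplx", gene_id = c("a", "b", "c", "d"),
                stoichiometry = c(4L, 3L, 2L, 1L), operon_id = "op1")
  audit2 <- stoichiometry_audit(prod2, cx2)
  expect_equal(audit2$complexes$spearman, -1)
})

test_that("complexes with fewer than two quantified subunits are skipped", {
  prod <- tibble(gene_id = c("a", "b"), condition = "control",
                 rpf_rpkm = c(100, 0), mrna_rpkm = 10, te = 1,
                 unstable = FALSE, production = c(100, 0))
  cx <- tibble(complex = "solo", gene_id = c("a", "b"),
               stoichiometry = c(1L, 1L), operon_id = "op")
  audit <- stoichiometry_audit(prod, cx)
  expect_equal(nrow(audit$skipped), 1)
  expect_equal(nrow(audit$complexes), 0)
})

test_that("equal subunit fold changes are never flagged disproportionate", {
  prod <- tidyr::expand_grid(gene_id = c("a", "b", "c"),
                             condition = c("control", "heat")) %>%
    mutate(base = c(300, 300, 100, 100, 100, 100)[seq_len(6)],
           production = ifelse(condition == "heat", base * 0.7, base),
           rpf_rpkm = production, mrna_rpkm = 10, te = 1, unstable = FALSE)
  cx <- tibble(complex = "cplx", gene_id = c("a", "b", "c"),
               stoichiometry = c(3L, 1L, 1L), operon_id = "op")
  audit <- stoichiometry_audit(prod %>% select(-base), cx)
  expect_false(any(audit$complexes$disproportionate))
})

test_that("operon densities proportional to stoichiometry are recovered", {
  cfg <- sim_config(seed = 63, n_genes = 20,
                    n_per_class = c(null = 20L), depth = 2000,
                    dispersion = 1e-3, altorf_gene = FALSE,
                    n_quadruplex_genes = c(utr5 = 0L, cds = 0L, utr3 = 0L))
  sim <- simulate_experiment(cfg)
  counts <- count_reads(sim$reads, sim$models, "cds")
  prod <- protein_production(counts, sim$models) %>%
    filter(gene_id %in% cfg$plastid_complexes$gene_id,
           condition == "control")
  audit <- stoichiometry_audit(prod, cfg$plastid_complexes)
  err <- abs(audit$subunits$obs_ratio / audit$subunits$exp_ratio - 1)
  expect_lt(max(err), 0.15)
  expect_equal(audit$complexes$spearman[1] > 0.8, TRUE)
})

test_that("abundance correlation is a rank correlation with low-n warning", {
  prod <- tibble(gene_id = paste0("g", 1:20), condition = "control",
                 production = exp(rnorm(20)))
  ab <- tibble(gene_id = prod$gene_id, abundance = prod$production)
  expect_equal(abundance_correlation(prod, ab)$rho, 1)
  # a monotone transform leaves the rank correlation at 1
  ab2 <- ab %>% mutate(abundance = log(abundance + 10))
  expect_equal(abundance_correlation(prod, ab2)$rho, 1)
  expect_warning(res <- abundance_correlation(prod[1:3, ], ab[1:3, ]),
                 "fewer than 5")
  expect_true(res$low_n)
})
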