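# riboheat

Joint analysis of ribosome profiling (Ribo-Seq) and RNA-Seq for
two-condition stress experiments, built around the question of how plants
reprogram gene expression under prolonged heat: which genes change at the
level of the transcript pool, which at the level of translation, and
which sequence features travel with the translational response.

The package implements, as tested reusable functions on tidy data frames:

* **Quantification** — gene-level counting in transcript space by the
  read-midpoint rule, rpm/rpkm normalization, spike-in based detection
  limits, and half-transcript symmetry statistics.
* **Differential classification** — a negative-binomial Wald test with
  trend-shared dispersion (median-of-ratios size factors, BH-FDR 0.1),
  applied separately to mRNA and footprint counts and combined into the
  three-way partition: changed in both, mRNA only, or footprints only
  (translational regulation).
* **Folding-energy metaprofiles** — sliding 39-nt window minimum-energy
  profiles around start codons from a built-in, exactly verifiable
  weighted base-pair maximization (G-C = 3, A-U = 2, G-U = 1, hairpin
  >= 3 nt), with group averaging and a Mann-Whitney contrast on the
  [-100, 0) upstream region.
* **G-quadruplex analysis** — a scanner for the grammar
  `Gk N1-7 Gk N1-7 Gk N1-7 Gk` (tiers G2/G3/G4), region stratification,
  -200..+250 flanking footprint metaprofiles normalized to mRNA, a
  calibrated signed-rank condition test, fold-change association, and a
  3'UTR stability check.
* **Alternative-ORF discovery** — robust-z asymmetry screening, CUSUM
  change-point localization in coverage, in-frame ATG calling with
  peptide translation and charged-residue content, and heat-shock
  promoter element (AGAAnnTTCT) scanning.
* **Plastid stoichiometry** — protein production from CDS footprint
  density (rpf rpkm, or normalized to operon-shared mRNA), audited
  against declared complex stoichiometries with Spearman concordance and
  disproportionality flags.
* **A synthetic-data generator** — a fully specified toy transcriptome
  and 2x2 read simulator with planted truth for every stage (regulation
  classes, quadruplexes with a clean negative set, an A/U-rich upstream
  group, an 88-residue alternative ORF behind a coverage step at position
  2195, a spike-in ladder with a dropout floor, and an ATP-synthase-like
  operon pair).

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

Simulate an experiment, classify regulation, scan quadruplexes, and call
the planted alternative ORF:

```r
library(riboheat)
library(dplyr)

cfg <- sim_config(seed = 42, n_genes = 200, depth = 400)
sim <- simulate_experiment(cfg)

counts <- count_reads(sim$reads, sim$models, region = "cds")
limits <- detection_limit(spikein_rpkm(sim$spikeins, sim$reads))
de <- translatome_diffexpr(counts, fdr = 0.1, limits = limits)
de
#> riboheat differential analysis: 206 genes tested (FDR 0.1), 0 below detection
#>   class              n
#> 1 both_down         16
#> 2 both_up           15
#> 3 mrna_only_down    15
#> 4 mrna_only_up      16
#> 5 rpf_only_down     18
#> 6 rpf_only_up       32
#> 7 unchanged         94
```

The planted design had 15 genes per `both`/`mrna_only` class, 30
`rpf_only_up`, 15 `rpf_only_down` and the rest null: the recovered class
counts sit on the planted truth, with the expected handful of
false/missed calls at FDR 0.1.

```r
hits <- scan_quadruplexes(sim$models, tiers = "G2")
count(hits, region)
#>   region     n
#> 1 cds      320
#> 2 utr3      63
#> 3 utr5      54

fl <- flank_metaprofile(filter(hits, region == "utr5",
                               gene_id %in% sim$truth$quadruplexes$gene_id),
                        sim$reads, sim$models)
fl
#> riboheat flanking metaprofile: 30 gene(s), signed-rank p = 0.0119 over 321 positions
autoplot(fl)   # heat vs control RPF/mRNA curves around the quadruplex start
```

CDS hits are abundant (G2 motifs are common in coding sequence at this
GC content), while the UTR hit sets are dominated by the 30 planted genes
per region; the stress-specific footprint elevation over the 5'UTR motifs
is detected by the paired test.

```r
g <- sim$truth$altorf$gene_id
m <- filter(sim$models, gene_id == g)
cov <- coverage_from_reads(filter(sim$reads, assay == "rpf",
                                  condition == "heat",
                                  transcript_id == m$transcript_id), m)
cp <- find_changepoint(cov$depth[[1]][(m$cds_start + 1):m$cds_end])
call_alt_orf(m, cp$changepoint) %>%
  select(gene_id, changepoint, alt_start, peptide_len, frac_positive, status)
#>   gene_id  changepoint alt_start peptide_len frac_positive status
#> 1 gene0106        2195      2196          88         0.398 ok
```

The stress footprint step is localized at CDS position 2195, the first
in-frame ATG sits at 2196, and translating from it yields the planted
88-residue peptide with ~40% positively charged residues.

```r
prod <- protein_production(counts, sim$models) %>%
  filter(gene_id %in% sim$truth$complexes$gene_id)
stoichiometry_audit(prod, sim$truth$complexes)
#> riboheat stoichiometry audit
#>   complex      condition spearman     n fc_spread disproportionate
#> 1 atp_synthase control      0.828     6      3.43 TRUE
#> 2 atp_synthase heat         0.828     6      3.43 TRUE
```

Subunit production tracks the planted 3:1:1:1 / 3:1 stoichiometry
(Spearman 0.828 is the ceiling under the tied ranks), and the subunit
whose output was disproportionately reduced under heat pushes the
fold-change spread past the 2-fold flag.

`run_demo(out_dir, config)` chains every stage on one simulated
experiment and writes all stage tables plus a ground-truth comparison
summary.

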