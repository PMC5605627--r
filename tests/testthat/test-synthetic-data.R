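test_that("configuration invariants are enforced", {
  expect_error(SimConfig(mechanism_fractions = c(mrna_localization = 0.6,
                                                 unlocalized = 0.5)),
               "sum to 1")
  expect_error(SimConfig(mechanism_fractions = c(bogus = 1)), "names")
  expect_error(SimConfig(n_replicates = 1), "n_replicates")
  expect_error(SimConfig(frame0_bias = 0.2), "frame0_bias")
  expect_error(SimConfig(loc_effect_log2 = 0.8), "loc_effect_log2")
})

test_that("mechanism quota is deterministic and exact up to rounding", {
  g <- simulateGenes(SimConfig(n_genes = 100,
                               mechanism_fractions = c(mrna_localization = 1)))
  expect_equal(nrow(g), 100)
  expect_true(all(g$rna_loc_log2fc[g$biotype == "coding"] == 2.0))

  g2 <- simulateGenes(SimConfig(
    n_genes = 10000,
    mechanism_fractions = c(mrna_localization = 0.1, unlocalized = 0.9)))
  expect_identical(sum(g2$mechanism == "mrna_localization"), 1000L)

  cfg <- tiny_config()
  expect_identical(simulateGenes(cfg), simulateGenes(cfg))
})

test_that("every gene's true effects satisfy its mechanism's sign pattern", {
  g <- simulateGenes(SimConfig(n_genes = 1000, seed = 5))
  coding <- g[g$biotype == "coding", ]
  with(coding[coding$mechanism == "mrna_localization", ],
       expect_true(all(rna_loc_log2fc > 1 & prot_loc_log2fc > 1 &
                         ribo_loc_log2fc > 1)))
  with(coding[coding$mechanism == "intermediate", ],
       expect_true(all(rna_loc_log2fc > 0 & rna_loc_log2fc < 1 &
                         prot_loc_log2fc > 1)))
  with(coding[coding$mechanism == "protein_transport", ],
       expect_true(all(rna_loc_log2fc < 0 & ribo_loc_log2fc < 0 &
                         prot_loc_log2fc > 1)))
  with(coding[coding$mechanism == "local_translation", ],
       expect_true(all(rna_loc_log2fc < 0 & ribo_loc_log2fc > 1 &
                         prot_loc_log2fc > 1)))
  with(coding[coding$mechanism == "combination", ],
       expect_true(all(rna_loc_log2fc < 0 & ribo_loc_log2fc > 0 &
                         ribo_loc_log2fc < 1 & prot_loc_log2fc > 1)))
  with(coding[coding$mechanism == "soma_restricted", ],
       expect_true(all(rna_loc_log2fc < 0 & prot_loc_log2fc < -1)))
  with(g[g$mechanism == "unlocalized", ],
       expect_true(all(rna_loc_log2fc == 0 & prot_loc_log2fc == 0)))
  # lncRNAs carry no protein or translation effect and no CDS
  lnc <- g[g$biotype == "lncRNA", ]
  expect_true(all(lnc$cds_length == 0))
  expect_true(all(lnc$prot_loc_log2fc == 0 & lnc$ribo_loc_log2fc == 0))
  # CDS constraints for coding genes
  expect_true(all(coding$cds_length > 0 & coding$cds_length <= coding$tx_length))
  expect_true(all(coding$cds_length %% 3 == 0))
})

test_that("RNA counts follow the generative means and conserve depth", {
  cfg <- SimConfig(n_genes = 1000, rna_depth = 1e6, seed = 3,
                   mechanism_fractions = c(unlocalized = 1))
  g <- simulateGenes(cfg)
  x <- simulateRnaCounts(g, cfg)
  expect_identical(assayKind(x), "counts")
  # all-null bundle: empirical mean log2 ratio near zero
  fc <- log2((compartmentMeans(x, "neurite") + 0.5) /
             (compartmentMeans(x, "soma") + 0.5))
  expect_lt(abs(mean(fc)), 0.05)
  # per-replicate library size within 2% of the configured depth
  expect_true(all(abs(colSums(abundances(x)) / 1e6 - 1) < 0.02))

  zero <- simulateRnaCounts(g, SimConfig(n_genes = 1000, rna_depth = 0,
                                         mechanism_fractions = c(unlocalized = 1)))
  expect_true(all(abundances(zero) == 0))
})

test_that("null RNA log2 ratios center at zero across seeds", {
  mfc <- vapply(1:5, function(s) {
    cfg <- SimConfig(n_genes = 1000, rna_depth = 1e6, seed = s,
                     mechanism_fractions = c(unlocalized = 1))
    x <- simulateRnaCounts(simulateGenes(cfg), cfg)
    mean(log2((compartmentMeans(x, "neurite") + 0.5) /
              (compartmentMeans(x, "soma") + 0.5)))
  }, numeric(1))
  expect_true(all(abs(mfc) < 0.05))
})

test_that("footprints have the advertised length, frame and scaling structure", {
  cfg <- tiny_config(frame0_bias = 1.0)
  g <- simulateGenes(cfg)
  fp <- simulateFootprints(g, cfg)
  expect_true(all(fp$length >= 27 & fp$length <= 31))
  expect_true(all((fp$five_prime_offset + 12L) %% 3L == 0L))
  expect_true(all(fp$gene_id %in% g$gene_id[g$biotype == "coding"]))

  lnc_only <- g[g$biotype == "lncRNA", ]
  expect_warning(empty <- simulateFootprints(lnc_only, cfg), "no coding")
  expect_identical(nrow(empty), 0L)
})

test_that("uniform frame bias yields uniform frames", {
  cfg <- tiny_config(frame0_bias = 1 / 3, footprint_depth = 2e4, seed = 21)
  fp <- simulateFootprints(simulateGenes(cfg), cfg)
  frames <- (fp$five_prime_offset + 12L) %% 3L
  gof <- chisq.test(tabulate(frames + 1L, 3L))
  expect_gt(gof$p.value, 0.01)
})

test_that("protein intensities encode the localization effect and MNAR mask", {
  cfg <- tiny_config(protein_noise_sd = 0, missing_midpoint = -Inf)
  g <- simulateGenes(cfg)
  x <- simulateProteinIntensities(g, cfg)
  expect_false(anyNA(abundances(x)))
  d <- compartmentMeans(x, "neurite") - compartmentMeans(x, "soma")
  coding <- g[g$biotype == "coding", ]
  expect_equal(unname(d[coding$gene_id]), coding$prot_loc_log2fc)

  # same seed with missingness on: observed cells agree, and the true
  # values behind missing cells are lower on average than observed ones
  cfg2 <- tiny_config(n_genes = 1000)
  g2 <- simulateGenes(cfg2)
  complete <- abundances(simulateProteinIntensities(
    g2, tiny_config(n_genes = 1000, missing_midpoint = -Inf)))
  masked <- abundances(simulateProteinIntensities(g2, cfg2))
  nas <- is.na(masked)
  expect_gt(sum(nas), 0)
  expect_identical(masked[!nas], complete[!nas])
  expect_lt(mean(complete[nas]), mean(complete[!nas]))
})

test_that("missingness rate is non-increasing in binned true intensity", {
  cfg <- tiny_config(n_genes = 1500, seed = 8)
  g <- simulateGenes(cfg)
  complete <- abundances(simulateProteinIntensities(
    g, tiny_config(n_genes = 1500, seed = 8, missing_midpoint = -Inf)))
  masked <- abundances(simulateProteinIntensities(g, cfg))
  bins <- cut(complete, breaks = quantile(complete, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  rate <- tapply(is.na(masked), bins, mean)
  expect_true(all(diff(rate) <= 0.02))  # monotone up to binomial jitter
})

test_that("label-swap ratios track the true translation effect", {
  cfg <- tiny_config(silac_noise_sd = 0, silac_coverage = 1)
  g <- simulateGenes(cfg)
  s <- simulateSilac(g, cfg)
  truth <- setNames(g$ribo_loc_log2fc, g$gene_id)
  expect_equal(log2(s$ratio_fw), unname(truth[s$protein_id]))
  expect_equal(log2(s$ratio_rev), unname(truth[s$protein_id]))

  none <- simulateSilac(g, tiny_config(silac_coverage = 0))
  expect_identical(nrow(none), 0L)

  # Monte-Carlo: averaged log2 ratios are unbiased for the truth
  bias <- vapply(1:3, function(s) {
    cfg <- tiny_config(n_genes = 500, silac_noise_sd = 0.2,
                       silac_coverage = 1, seed = s)
    g <- simulateGenes(cfg)
    tab <- simulateSilac(g, cfg)
    agg <- labelswapAggregate(
      data.frame(protein_id = tab$protein_id, ratio = tab$ratio_fw),
      data.frame(protein_id = tab$protein_id, ratio = tab$ratio_rev))
    truth <- setNames(g$ribo_loc_log2fc, g$gene_id)
    mean(agg$avg_log2 - truth[agg$protein_id])
  }, numeric(1))
  expect_true(all(abs(bias) < 0.03))
})

test_that("circular junction generator realizes the flagged pattern", {
  cfg <- tiny_config(n_genes = 400, circ_fraction = 0.1, seed = 13)
  g <- simulateGenes(cfg)
  cj <- simulateCirc(g, cfg)
  expect_length(cj$flagged, 40)
  rec <- circLinearRatio(cj$circ, cj$linear)
  flag_rec <- rec[rec$gene_id %in% cj$flagged, ]
  # expected 10:1 neurite and 1:7 soma patterns dominate
  expect_gt(median(flag_rec$log2_cl_neurite), 1)
  expect_lt(median(flag_rec$log2_cl_soma), 0)

  none <- simulateCirc(g, tiny_config(n_genes = 400, circ_fraction = 0))
  expect_length(none$flagged, 0)
})

test_that("identical configuration reproduces a byte-identical bundle", {
  cfg <- tiny_config(n_genes = 100)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(b1@truth, b2@truth)
  expect_identical(abundances(b1@rna), abundances(b2@rna))
  expect_identical(b1@footprints, b2@footprints)
  expect_identical(abundances(b1@protein), abundances(b2@protein))
  expect_identical(b1@silac, b2@silac)
  expect_identical(abundances(b1@circ), abundances(b2@circ))
  expect_identical(abundances(b1@linear), abundances(b2@linear))
})

test_that("bundle TSV export writes every table with the documented layout", {
  dir <- withr::local_tempdir()
  b <- simulateBundle(tiny_config(n_genes = 50))
  writeBundle(b, dir)
  files <- c("annotation.tsv", "ground_truth.tsv", "rna_counts.tsv",
             "footprints.tsv", "protein_log2.tsv", "silac_ratios.tsv",
             "circ_counts.tsv", "linear_counts.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  ann <- read.delim(file.path(dir, "annotation.tsv"))
  expect_named(ann, c("gene_id", "biotype", "tx_length", "cds_length",
                      "strand"))
  rna <- readCompartmentMatrix(file.path(dir, "rna_counts.tsv"), "counts")
  expect_equal(abundances(rna), abundances(b@rna))
})
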