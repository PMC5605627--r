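test_that("enrichment agrees with the textbook t test on log2 values", {
  x <- cm(soma = matrix(c(4, 5, 6), 1), neurite = matrix(c(8, 10, 12), 1),
          ids = "g1")
  rec <- compartmentEnrichment(x, pseudocount = 0.001)
  expect_equal(rec$log2fc, log2(10.001 / 5.001), tolerance = 1e-10)
  oracle <- t.test(log2(c(8, 10, 12) + 0.001), log2(c(4, 5, 6) + 0.001),
                   var.equal = TRUE)
  expect_equal(rec$pvalue, oracle$p.value, tolerance = 1e-12)

  welch <- compartmentEnrichment(x, pseudocount = 0.001, var.equal = FALSE)
  oracle_w <- t.test(log2(c(8, 10, 12) + 0.001), log2(c(4, 5, 6) + 0.001))
  expect_equal(welch$pvalue, oracle_w$p.value, tolerance = 1e-12)
})

test_that("t-test agreement holds across random instances (both variants)", {
  set.seed(42)
  for (i in 1:20) {
    soma <- matrix(2^rnorm(3, 5, 1), 1)
    neurite <- matrix(2^rnorm(3, 5 + rnorm(1), 1), 1)
    x <- cm(soma = soma, neurite = neurite)
    for (ve in c(TRUE, FALSE)) {
      rec <- compartmentEnrichment(x, pseudocount = 0.5, var.equal = ve)
      oracle <- t.test(log2(neurite + 0.5), log2(soma + 0.5), var.equal = ve)
      expect_equal(rec$pvalue, oracle$p.value, tolerance = 1e-9)
    }
  }
})

test_that("degenerate variance and identical groups follow the conventions", {
  same <- cm(soma = matrix(c(5, 5, 5), 1), neurite = matrix(c(5, 5, 5), 1))
  rec <- compartmentEnrichment(same)
  expect_equal(rec$log2fc, 0)
  expect_equal(rec$pvalue, 1)

  diff <- cm(soma = matrix(c(5, 5, 5), 1), neurite = matrix(c(20, 20, 20), 1))
  rec2 <- compartmentEnrichment(diff, pseudocount = 1e-9)
  expect_true(rec2$degenerate)
  expect_equal(rec2$log2fc, 2, tolerance = 1e-6)
  expect_identical(rec2$pvalue, .Machine$double.xmin)
  expect_gt(rec2$pvalue, 0)
})

test_that("swapping compartment labels negates log2fc and keeps p-values", {
  set.seed(9)
  soma <- matrix(2^rnorm(60, 6, 1), 20)
  neurite <- matrix(2^rnorm(60, 6.5, 1), 20)
  a <- compartmentEnrichment(cm(soma = soma, neurite = neurite))
  b <- compartmentEnrichment(cm(soma = neurite, neurite = soma))
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$pvalue, a$pvalue, tolerance = 1e-12)
})

test_that("BH adjustment is the reference one, monotone and >= p", {
  set.seed(10)
  x <- cm(soma = matrix(2^rnorm(300, 6, 1), 100),
          neurite = matrix(2^rnorm(300, 6, 1), 100))
  rec <- compartmentEnrichment(x)
  expect_equal(rec$padj, p.adjust(rec$pvalue, "BH"))
  expect_true(all(rec$padj >= rec$pvalue))
  o <- order(rec$pvalue)
  expect_true(all(diff(rec$padj[o]) >= -1e-15))
})

test_that("localization calls use strict thresholds on fc and p", {
  rec <- data.frame(feature_id = letters[1:6],
                    log2fc = c(1.2, 1.2, -1.5, 1.0, -1.0, 0.2),
                    pvalue = c(0.01, 0.07, 0.001, 0.01, 0.04, 0.001))
  out <- classifyLocalized(rec)
  expect_identical(out$call,
                   c("neurite", "none", "soma", "none", "none", "none"))
})

test_that("missing replicates reduce per-feature group sizes sensibly", {
  m <- rbind(g1 = c(20, 20.5, NA, 24, 25, 24.5),
             g2 = c(20, 20.5, 19.5, 24, 25, 24.5))
  colnames(m) <- c(paste0("soma_", 1:3), paste0("neurite_", 1:3))
  rec <- compartmentEnrichment(CompartmentMatrix(m, kind = "log2intensity"))
  # NA-dropped test equals a t test on the observed values
  oracle <- t.test(m["g1", 4:6], m["g1", 1:2], var.equal = TRUE)
  expect_equal(rec$pvalue[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(rec$log2fc[1], mean(m["g1", 4:6]) - mean(m["g1", 1:2]))
})

test_that("true localization is recovered at the design effect size", {
  set.seed(31)
  n_loc <- 500; n_null <- 500
  mu <- rnorm(n_loc + n_null, 24, 1.5)
  fc <- c(rep(2, n_loc), rep(0, n_null))
  soma <- matrix(rnorm(3 * (n_loc + n_null), mu, 0.5), ncol = 3)
  neurite <- matrix(rnorm(3 * (n_loc + n_null), mu + fc, 0.5), ncol = 3)
  rec <- compartmentEnrichment(cm(soma = soma, neurite = neurite,
                                  kind = "log2intensity"))
  expect_gte(mean(rec$call[1:n_loc] == "neurite"), 0.9)
  expect_lt(mean(rec$call[(n_loc + 1):(n_loc + n_null)] != "none"), 0.02)
})

test_that("cross-layer correlation matches cor.test and its contracts", {
  a <- enrich_rec(letters[1:3], c(1, 2, 3))
  b <- enrich_rec(letters[1:3], c(2, 4, 5))
  res <- crossLayerCorrelation(a, b)
  oracle <- cor.test(c(1, 2, 3), c(2, 4, 5))
  expect_equal(res$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$pvalue, oracle$p.value, tolerance = 1e-12)
  expect_identical(res$n, 3L)

  expect_equal(crossLayerCorrelation(a, a)$r, 1)
  neg <- enrich_rec(letters[1:3], -c(1, 2, 3))
  expect_equal(crossLayerCorrelation(a, neg)$r, -1)
  expect_error(crossLayerCorrelation(a[1:2, ], b), "at least 3")
})

test_that("delta-delta-Ct reproduces the worked examples", {
  r <- deltaDeltaCt(c(neurite = 20, soma = 24), c(neurite = 15, soma = 15))
  expect_equal(r$ddct, -4)
  expect_equal(r$relative_expression, 16)

  expect_equal(deltaDeltaCt(c(20, 20), c(20, 20))$relative_expression, 1)
  r2 <- deltaDeltaCt(c(neurite = 21, soma = 20), c(neurite = 16, soma = 14))
  expect_equal(r2$ddct, -1)
  expect_equal(r2$relative_expression, 2)
  expect_error(deltaDeltaCt(c(20, NA), c(15, 15)), "finite")
})
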