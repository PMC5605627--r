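# Synthetic compartmentalized multi-omics generator.
#
# Each table draws from its own RNG stream (seed + fixed per-table offset),
# so generating or skipping one table never perturbs another.

.STREAM <- c(genes = 0L, rna = 1L, footprints = 2L, protein = 3L,
             silac = 4L, circ = 5L, impute = 6L)

.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + .STREAM[[stream]])
  expr
}

#' Create a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two
#' compartments (soma, neurite) in 3 biological replicates; negative-binomial
#' RNA counts; ribosome footprints of 27-31 nt with a strong translated-frame
#' bias; log-normal protein intensities with intensity-dependent (MNAR)
#' missingness; and forward/reverse label-swap ratio pairs with partial
#' coverage.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per compartment (>= 2).
#' @param mechanism_fractions named fractions over the mechanism taxonomy
#'   (mrna_localization, intermediate, protein_transport, local_translation,
#'   combination, soma_restricted, unlocalized); must sum to 1. Class counts
#'   are allocated by deterministic quota (largest remainder), not sampled.
#'   The defaults balance neurite- and soma-directed transcript mass, so
#'   depth-scaled libraries stay globally comparable and unlocalized genes
#'   center at log2FC 0, as the study's unlocalized controls do.
#' @param rna_depth,footprint_depth expected reads / footprints per library.
#' @param frame0_bias probability that a footprint's P-site falls in frame 0
#'   (remainder split equally over frames 1 and 2); in [1/3, 1].
#' @param loc_effect_log2 true |log2FC| for fully localized features (> 1 so
#'   every mechanism's sign pattern is representable).
#' @param protein_noise_sd replicate SD of log2 protein intensity.
#' @param rna_dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param missing_steepness,missing_midpoint logistic missingness curve:
#'   P(missing) = plogis((midpoint - intensity) / steepness). Set
#'   \code{missing_midpoint = -Inf} to disable missingness.
#' @param silac_noise_sd,silac_coverage log2 noise SD of each label-swap
#'   ratio and the fraction of proteins quantified at all.
#' @param lnc_fraction fraction of genes emitted as lncRNA (no CDS, no
#'   protein).
#' @param circ_fraction fraction of genes flagged neurite-preferential in
#'   the circular/linear junction generator.
#' @param seed base RNG seed.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- SimConfig(n_genes = 200, seed = 7)
#' genes <- simulateGenes(cfg)
#' table(genes$mechanism)
#' @export
SimConfig <- function(n_genes = 2000L,
                      n_replicates = 3L,
                      mechanism_fractions = c(mrna_localization = 0.06,
                                              intermediate = 0.05,
                                              protein_transport = 0.035,
                                              local_translation = 0.015,
                                              combination = 0.02,
                                              soma_restricted = 0.24,
                                              unlocalized = 0.58),
                      rna_depth = 1e6,
                      footprint_depth = 2e5,
                      frame0_bias = 0.85,
                      loc_effect_log2 = 2.0,
                      protein_noise_sd = 0.5,
                      rna_dispersion = 0.05,
                      missing_steepness = 1.0,
                      missing_midpoint = 21,
                      silac_noise_sd = 0.25,
                      silac_coverage = 0.25,
                      lnc_fraction = 0.10,
                      circ_fraction = 0.05,
                      seed = 1L) {
  if (loc_effect_log2 <= 1)
    stop("loc_effect_log2 must exceed 1 so localized features clear the ",
         "twofold call threshold in truth")
  new("SimConfig",
      n_genes = as.integer(n_genes),
      n_replicates = as.integer(n_replicates),
      mechanism_fractions = mechanism_fractions,
      rna_depth = rna_depth, footprint_depth = footprint_depth,
      frame0_bias = frame0_bias, loc_effect_log2 = loc_effect_log2,
      protein_noise_sd = protein_noise_sd, rna_dispersion = rna_dispersion,
      missing_steepness = missing_steepness,
      missing_midpoint = missing_midpoint,
      silac_noise_sd = silac_noise_sd, silac_coverage = silac_coverage,
      lnc_fraction = lnc_fraction, circ_fraction = circ_fraction,
      seed = as.integer(seed))
}

# largest-remainder quota: class counts are exact up to rounding, never
# multinomially sampled, so they are directly testable
.quota <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[take] <- cnt[take] + 1
  }
  as.integer(cnt)
}

#' Simulate ground-truth genes
#'
#' Assigns each gene a localization mechanism by deterministic quota over
#' \code{mechanism_fractions}, then derives the mechanism's defining pattern
#' of true RNA / translation / protein neurite-vs-soma log2 fold changes:
#' fully localized axes get \code{+-loc_effect_log2}; the "moderate" axes of
#' the intermediate and combination classes get +0.5 (the midpoint of the
#' (0, 1) log2FC band that defines them); protein-side mechanisms with
#' soma-leaning RNA get -0.5.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with one row per gene: \code{gene_id}, \code{biotype}
#'   (coding / lncRNA), \code{tx_length}, \code{cds_length} (0 for lncRNA),
#'   \code{strand}, \code{mechanism}, \code{base_expression} and the true
#'   \code{rna_loc_log2fc}, \code{ribo_loc_log2fc}, \code{prot_loc_log2fc}.
#' @export
simulateGenes <- function(config) {
  validObject(config)
  n <- config@n_genes
  E <- config@loc_effect_log2
  f <- setNames(numeric(length(.MECHANISMS)), .MECHANISMS)
  f[names(config@mechanism_fractions)] <- config@mechanism_fractions
  counts <- .quota(f, n)
  mech <- rep(.MECHANISMS, counts)

  .with_stream(config@seed, "genes", {
    tx <- pmin(pmax(round(2^rnorm(n, log2(2500), 0.6)), 300L), 20000L)
    cds <- 3L * pmax(floor(runif(n, 0.4, 0.9) * tx / 3), 30L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    base <- 2^rnorm(n, 4, 1.5)
    biotype <- rep("coding", n)
    eligible <- which(mech %in% c("unlocalized", "soma_restricted",
                                  "mrna_localization"))
    n_lnc <- min(round(config@lnc_fraction * n), length(eligible))
    if (n_lnc > 0)
      biotype[sample(eligible, n_lnc)] <- "lncRNA"
  })
  cds[biotype == "lncRNA"] <- 0L

  pattern <- list(mrna_localization = c(E, E, E),
                  intermediate      = c(0.5, 0.5, E),
                  protein_transport = c(-0.5, -0.5, E),
                  local_translation = c(-0.5, E, E),
                  combination       = c(-0.5, 0.5, E),
                  soma_restricted   = c(-E, -E, -E),
                  unlocalized       = c(0, 0, 0))
  fc <- do.call(rbind, pattern[mech])
  fc[biotype == "lncRNA", 2:3] <- 0  # no protein product, no translation

  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             biotype = biotype, tx_length = tx, cds_length = cds,
             strand = strand, mechanism = mech, base_expression = base,
             rna_loc_log2fc = fc[, 1], ribo_loc_log2fc = fc[, 2],
             prot_loc_log2fc = fc[, 3],
             stringsAsFactors = FALSE)
}

# NB draw that degrades to Poisson at dispersion 0
.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

.count_matrix <- function(soma_rate, neurite_rate, depth, R, dispersion,
                          ids) {
  scale_s <- if (sum(soma_rate) > 0) depth / sum(soma_rate) else 0
  scale_n <- if (sum(neurite_rate) > 0) depth / sum(neurite_rate) else 0
  n <- length(soma_rate)
  m <- matrix(0L, n, 2L * R,
              dimnames = list(ids, c(paste0("soma_", seq_len(R)),
                                     paste0("neurite_", seq_len(R)))))
  for (r in seq_len(R)) {
    m[, r] <- .rcounts(n, soma_rate * scale_s, dispersion)
    m[, R + r] <- .rcounts(n, neurite_rate * scale_n, dispersion)
  }
  m
}

#' Simulate RNA-seq counts per compartment
#'
#' Per-gene soma rates are proportional to transcript abundance times
#' transcript length (fragment counting); neurite rates multiply in
#' \code{2^rna_loc_log2fc}. Each library is scaled so its expected total is
#' \code{rna_depth}, then counts are drawn NB(mu, dispersion).
#'
#' @param genes output of [simulateGenes()].
#' @param config the [SimConfig-class].
#' @return [CompartmentMatrix-class] of kind \code{"counts"}.
#' @export
simulateRnaCounts <- function(genes, config) {
  stopifnot(nrow(genes) > 0)
  soma <- genes$base_expression * genes$tx_length
  neur <- soma * 2^genes$rna_loc_log2fc
  .with_stream(config@seed, "rna",
    CompartmentMatrix(.count_matrix(soma, neur, config@rna_depth,
                                    config@n_replicates,
                                    config@rna_dispersion, genes$gene_id),
                      kind = "counts"))
}

#' Simulate ribosome footprints
#'
#' Coding genes receive Poisson footprint totals proportional to
#' \code{base_expression * cds_length} (times \code{2^ribo_loc_log2fc} in
#' neurites), each library scaled to \code{footprint_depth}. Every footprint
#' picks a codon uniformly within the CDS and a read length from 27-31 nt
#' (31-mers at 5\% deliberately, so the downstream 27-30 filter has work to
#' do); its P-site lands in frame 0 with probability \code{frame0_bias},
#' otherwise in frame 1 or 2 equiprobably. The table emits raw 5' offsets
#' (P-site minus 12 nt), leaving the P-site correction to the analysis.
#'
#' @inheritParams simulateRnaCounts
#' @return data.frame of footprint records: \code{gene_id},
#'   \code{five_prime_offset} (0-based, relative to CDS start),
#'   \code{length}, \code{strand}, \code{compartment}, \code{replicate}.
#' @export
simulateFootprints <- function(genes, config) {
  coding <- genes[genes$biotype == "coding" & genes$cds_length > 0, ]
  empty <- data.frame(gene_id = character(), five_prime_offset = integer(),
                      length = integer(), strand = character(),
                      compartment = character(), replicate = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(coding) == 0) {
    warning("no coding genes: footprint table is empty")
    return(empty)
  }
  R <- config@n_replicates
  soma <- coding$base_expression * coding$cds_length
  neur <- soma * 2^coding$ribo_loc_log2fc
  lens <- 27:31
  len_p <- c(0.15, 0.25, 0.35, 0.20, 0.05)
  b <- config@frame0_bias
  .with_stream(config@seed, "footprints", {
    cnt <- .count_matrix(soma, neur, config@footprint_depth, R, 0,
                         coding$gene_id)
    total <- sum(cnt)
    if (total == 0) empty
    else {
      idx <- rep(rep(seq_len(nrow(coding)), 2L * R), as.vector(cnt))
      samp <- rep(rep(seq_len(2L * R), each = nrow(coding)), as.vector(cnt))
      codon <- floor(runif(total) * (coding$cds_length[idx] %/% 3L))
      frame <- ifelse(runif(total) < b, 0L,
                      ifelse(runif(total) < 0.5, 1L, 2L))
      data.frame(gene_id = coding$gene_id[idx],
                 five_prime_offset = as.integer(3L * codon + frame - 12L),
                 length = sample(lens, total, replace = TRUE, prob = len_p),
                 strand = coding$strand[idx],
                 compartment = rep(c("soma", "neurite"), each = R)[samp],
                 replicate = ((samp - 1L) %% R) + 1L,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Simulate protein log2 intensities with MNAR missingness
#'
#' Log2 intensity for coding gene g in sample s is
#' \code{20 + log2(base_expression_g) + prot_loc_log2fc_g * [s is neurite]
#' + Normal(0, protein_noise_sd)}. Each cell then goes missing with
#' probability \code{plogis((missing_midpoint - intensity) /
#' missing_steepness)} — low-abundance proteins drop out preferentially,
#' the missing-not-at-random structure that motivates down-shifted
#' imputation.
#'
#' @inheritParams simulateRnaCounts
#' @return [CompartmentMatrix-class] of kind \code{"log2intensity"} with NA
#'   for missing cells.
#' @export
simulateProteinIntensities <- function(genes, config) {
  coding <- genes[genes$biotype == "coding", ]
  if (nrow(coding) == 0) stop("no coding genes to simulate proteins for")
  R <- config@n_replicates
  n <- nrow(coding)
  mu <- 20 + log2(coding$base_expression)
  .with_stream(config@seed, "protein", {
    m <- matrix(NA_real_, n, 2L * R,
                dimnames = list(coding$gene_id,
                                c(paste0("soma_", seq_len(R)),
                                  paste0("neurite_", seq_len(R)))))
    for (r in seq_len(R)) {
      m[, r] <- mu + rnorm(n, 0, config@protein_noise_sd)
      m[, R + r] <- mu + coding$prot_loc_log2fc +
        rnorm(n, 0, config@protein_noise_sd)
    }
    p_miss <- plogis((config@missing_midpoint - m) /
                       config@missing_steepness)
    m[runif(length(m)) < p_miss] <- NA_real_
    CompartmentMatrix(m, kind = "log2intensity")
  })
}

#' Simulate label-swap SILAC ratio pairs
#'
#' A random subset (\code{silac_coverage}) of coding genes is quantified.
#' Forward (H/M) and reverse (M/H) ratios are independent noisy readouts of
#' the true translation-rate ratio: \code{2^(ribo_loc_log2fc + eps)},
#' eps ~ Normal(0, silac_noise_sd).
#'
#' @inheritParams simulateRnaCounts
#' @return data.frame: \code{protein_id}, \code{ratio_fw}, \code{ratio_rev}.
#' @export
simulateSilac <- function(genes, config) {
  coding <- genes[genes$biotype == "coding", ]
  if (nrow(coding) == 0) stop("no coding genes to simulate SILAC for")
  .with_stream(config@seed, "silac", {
    k <- round(config@silac_coverage * nrow(coding))
    if (k == 0) {
      data.frame(protein_id = character(), ratio_fw = numeric(),
                 ratio_rev = numeric(), stringsAsFactors = FALSE)
    } else {
      pick <- sort(sample(nrow(coding), k))
      fc <- coding$ribo_loc_log2fc[pick]
      data.frame(protein_id = coding$gene_id[pick],
                 ratio_fw = 2^(fc + rnorm(k, 0, config@silac_noise_sd)),
                 ratio_rev = 2^(fc + rnorm(k, 0, config@silac_noise_sd)),
                 stringsAsFactors = FALSE)
    }
  })
}

#' Simulate circular / linear junction counts
#'
#' A \code{circ_fraction} subset of genes is flagged neurite-preferential
#' for its circular isoform, with expected junction counts mirroring the
#' Ephb2-like pattern: circ:linear 10:1 in neurites and 1:7 in soma. All
#' other genes keep an identical expected circ/linear ratio (1:5) in both
#' compartments, each isoform scaling with the gene's RNA localization.
#' Counts are Poisson.
#'
#' @inheritParams simulateRnaCounts
#' @return list with [CompartmentMatrix-class] elements \code{circ} and
#'   \code{linear} (junction counts) and \code{flagged}, the character ids
#'   of the neurite-preferential genes.
#' @export
simulateCirc <- function(genes, config) {
  stopifnot(nrow(genes) > 0)
  R <- config@n_replicates
  n <- nrow(genes)
  .with_stream(config@seed, "circ", {
    k <- round(config@circ_fraction * n)
    flagged <- if (k > 0) sort(sample(n, k)) else integer()
    unit <- pmax(2, genes$base_expression / 4)
    comp_scale <- 2^genes$rna_loc_log2fc
    circ_s <- unit * 0.2
    lin_s <- unit
    circ_n <- unit * 0.2 * comp_scale
    lin_n <- unit * comp_scale
    circ_s[flagged] <- unit[flagged]
    lin_s[flagged] <- 7 * unit[flagged]
    circ_n[flagged] <- 10 * unit[flagged]
    lin_n[flagged] <- unit[flagged]
    draw <- function(soma, neur) {
      m <- matrix(0L, n, 2L * R,
                  dimnames = list(genes$gene_id,
                                  c(paste0("soma_", seq_len(R)),
                                    paste0("neurite_", seq_len(R)))))
      for (r in seq_len(R)) {
        m[, r] <- rpois(n, soma)
        m[, R + r] <- rpois(n, neur)
      }
      CompartmentMatrix(m, kind = "counts")
    }
    list(circ = draw(circ_s, circ_n), linear = draw(lin_s, lin_n),
         flagged = genes$gene_id[flagged])
  })
}

#' Simulate a complete multi-omics bundle
#'
#' Runs every generator off the shared configuration and packs the results,
#' together with the ground truth, into a [SimBundle-class].
#'
#' @param config a [SimConfig-class].
#' @return A [SimBundle-class].
#' @examples
#' b <- simulateBundle(SimConfig(n_genes = 100, rna_depth = 1e4,
#'                               footprint_depth = 1e4, seed = 3))
#' b
#' @export
simulateBundle <- function(config) {
  genes <- simulateGenes(config)
  cj <- simulateCirc(genes, config)
  genes$circ_neurite_preferential <- genes$gene_id %in% cj$flagged
  new("SimBundle",
      truth = genes,
      rna = simulateRnaCounts(genes, config),
      footprints = simulateFootprints(genes, config),
      protein = simulateProteinIntensities(genes, config),
      silac = simulateSilac(genes, config),
      circ = cj$circ, linear = cj$linear,
      config = config)
}

#' Write a bundle to a directory of TSV files
#'
#' Emits \code{annotation.tsv} (observable gene annotation),
#' \code{ground_truth.tsv} (mechanisms and true effects, kept separate),
#' \code{rna_counts.tsv}, \code{footprints.tsv}, \code{protein_log2.tsv},
#' \code{silac_ratios.tsv}, \code{circ_counts.tsv}, \code{linear_counts.tsv}.
#'
#' @param bundle a [SimBundle-class].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  ann <- bundle@truth[, c("gene_id", "biotype", "tx_length", "cds_length",
                          "strand")]
  w(ann, "annotation.tsv")
  w(bundle@truth, "ground_truth.tsv")
  writeCompartmentMatrix(bundle@rna, file.path(dir, "rna_counts.tsv"))
  w(bundle@footprints, "footprints.tsv")
  writeCompartmentMatrix(bundle@protein, file.path(dir, "protein_log2.tsv"))
  w(bundle@silac, "silac_ratios.tsv")
  writeCompartmentMatrix(bundle@circ, file.path(dir, "circ_counts.tsv"))
  writeCompartmentMatrix(bundle@linear, file.path(dir, "linear_counts.tsv"))
  invisible(dir)
}
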