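#' Neurite-versus-soma enrichment statistics
#'
#' For every feature, the neurite/soma log2 fold change and a two-sided
#' p-value from a two-sample t test on per-replicate log2 values. Linear
#' abundances (counts, RPKM) are stabilized with a pseudocount before the
#' log: \code{log2fc = log2((mean_N + pc) / (mean_S + pc))}; log2-intensity
#' matrices are used directly and the fold change is the difference of
#' compartment means.
#'
#' The default test pools the two compartment variances (Student t). At the
#' 2-4 replicates typical of compartment fractionation experiments the
#' Satterthwaite approximation behind Welch's test is noticeably
#' conservative, while the pooled test is exact under the equal-variance
#' log-normal noise model; \code{var.equal = FALSE} switches to Welch for
#' data where the compartments' variances genuinely differ. Features whose
#' replicate values are constant within both compartments get p = 1 when
#' the means agree, and otherwise the smallest representable double with
#' \code{degenerate = TRUE} (a zero-variance mean difference is evidence,
#' but p = 0 is never emitted).
#'
#' @param x a [CompartmentMatrix-class]; at least 2 replicates per
#'   compartment.
#' @param pseudocount added to linear-scale values before log2 (> 0);
#'   ignored for log2-intensity data.
#' @param var.equal pool the compartment variances (default) or use the
#'   Welch/Satterthwaite test.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{log2fc}, \code{pvalue}, \code{padj} (Benjamini-Hochberg),
#'   \code{mean_abundance} (input scale, averaged over all samples),
#'   \code{degenerate}, and \code{call} initialized by
#'   [classifyLocalized()] at its default thresholds.
#' @examples
#' m <- matrix(c(4, 5, 6, 8, 10, 12), 1,
#'             dimnames = list("g1", c(paste0("soma_", 1:3),
#'                                     paste0("neurite_", 1:3))))
#' compartmentEnrichment(CompartmentMatrix(m, kind = "rpkm"))
#' @export
compartmentEnrichment <- function(x, pseudocount = 0.5, var.equal = TRUE) {
  stopifnot(is(x, "CompartmentMatrix"))
  comp <- compartments(x)
  nN <- sum(comp == "neurite"); nS <- sum(comp == "soma")
  if (nN < 2 || nS < 2)
    stop("need >= 2 replicates per compartment for enrichment testing")
  v <- abundances(x)
  if (assayKind(x) == "log2intensity") {
    lv <- v
    log2fc <- rowMeans(v[, comp == "neurite", drop = FALSE], na.rm = TRUE) -
      rowMeans(v[, comp == "soma", drop = FALSE], na.rm = TRUE)
  } else {
    if (pseudocount <= 0)
      stop("pseudocount must be > 0 for linear-scale data")
    if (anyNA(v))
      stop("missing values in ", assayKind(x), " data; impute first")
    lv <- log2(v + pseudocount)
    # FC on the linear scale (ratio of compartment means); the t test runs
    # on the variance-stabilized per-replicate log2 values below
    log2fc <- log2(
      (rowMeans(v[, comp == "neurite", drop = FALSE]) + pseudocount) /
      (rowMeans(v[, comp == "soma", drop = FALSE]) + pseudocount))
  }
  lN <- lv[, comp == "neurite", drop = FALSE]
  lS <- lv[, comp == "soma", drop = FALSE]
  # log2-intensity matrices may carry sporadic missing replicates (cells
  # imputeMissing(scope = "compartment") left alone); per-feature group
  # sizes are the observed counts
  nNg <- rowSums(!is.na(lN)); nSg <- rowSums(!is.na(lS))
  mN <- rowMeans(lN, na.rm = TRUE); mS <- rowMeans(lS, na.rm = TRUE)
  vN <- apply(lN, 1, var, na.rm = TRUE)
  vS <- apply(lS, 1, var, na.rm = TRUE)

  if (var.equal) {
    df <- nNg + nSg - 2
    sp2 <- (ifelse(nNg >= 2, (nNg - 1) * vN, 0) +
            ifelse(nSg >= 2, (nSg - 1) * vS, 0)) / df
    se <- sqrt(sp2 * (1 / nNg + 1 / nSg))
    valid <- nNg >= 1 & nSg >= 1 & df >= 1
  } else {
    se2 <- vN / nNg + vS / nSg
    df <- se2^2 / ((vN / nNg)^2 / (nNg - 1) + (vS / nSg)^2 / (nSg - 1))
    se <- sqrt(se2)
    valid <- nNg >= 2 & nSg >= 2
  }
  tstat <- (mN - mS) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- valid & (se == 0 | !is.finite(se))
  fc0 <- !is.na(log2fc) & log2fc == 0
  p[degenerate & !fc0] <- .Machine$double.xmin
  p[degenerate & fc0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[!valid] <- NA_real_
  log2fc[!is.finite(log2fc)] <- NA_real_

  rec <- data.frame(feature_id = rownames(v),
                    log2fc = log2fc,
                    pvalue = p,
                    padj = p.adjust(p, method = "BH"),
                    mean_abundance = rowMeans(v, na.rm = TRUE),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  classifyLocalized(rec)
}

#' Localization calls at fold-change and significance thresholds
#'
#' Three-way call with strict inequalities, following the volcano-plot
#' convention: \code{"neurite"} when log2fc > fc_thresh and p < p_thresh,
#' \code{"soma"} when log2fc < -fc_thresh and p < p_thresh, otherwise
#' \code{"none"}. Defaults (twofold, p < 0.05) are the thresholds used for
#' all omics layers.
#'
#' @param records data.frame with \code{log2fc} and \code{pvalue} columns.
#' @param fc_thresh log2 fold-change threshold (default 1 = twofold).
#' @param p_thresh raw p-value threshold (default 0.05).
#' @return `records` with the \code{call} column (re)computed.
#' @export
classifyLocalized <- function(records, fc_thresh = 1.0, p_thresh = 0.05) {
  stopifnot(all(c("log2fc", "pvalue") %in% names(records)))
  call <- rep("none", nrow(records))
  sig <- !is.na(records$pvalue) & records$pvalue < p_thresh &
    !is.na(records$log2fc)
  call[sig & records$log2fc > fc_thresh] <- "neurite"
  call[sig & records$log2fc < -fc_thresh] <- "soma"
  records$call <- call
  records
}

#' Pearson correlation of enrichment between two omics layers
#'
#' Joins two enrichment tables on \code{feature_id} and correlates their
#' log2 fold changes; the p-value comes from the usual t transform of r on
#' n - 2 degrees of freedom.
#'
#' @param records_a,records_b data.frames with \code{feature_id} and
#'   \code{log2fc}.
#' @return list(\code{r}, \code{pvalue}, \code{n}).
#' @export
crossLayerCorrelation <- function(records_a, records_b) {
  m <- merge(records_a[, c("feature_id", "log2fc")],
             records_b[, c("feature_id", "log2fc")],
             by = "feature_id", suffixes = c("_a", "_b"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3)
    stop("need at least 3 shared features; got ", nrow(m))
  ct <- stats::cor.test(m$log2fc_a, m$log2fc_b, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = nrow(m))
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification against a reference RNA (typically rRNA):
#' \code{ddCt = (Ct_target,N - Ct_ref,N) - (Ct_target,S - Ct_ref,S)} and
#' relative neurite/soma expression \code{2^(-ddCt)}.
#'
#' @param target_ct,reference_ct numeric length-2 vectors of Ct values,
#'   named or ordered \code{c(neurite, soma)}.
#' @return list(\code{ddct}, \code{relative_expression}).
#' @examples
#' deltaDeltaCt(c(neurite = 20, soma = 24), c(neurite = 15, soma = 15))
#' @export
deltaDeltaCt <- function(target_ct, reference_ct) {
  pick <- function(x, w) {
    if (!is.null(names(x)) && all(c("neurite", "soma") %in% names(x)))
      x[[w]]
    else x[[match(w, c("neurite", "soma"))]]
  }
  vals <- c(pick(target_ct, "neurite"), pick(target_ct, "soma"),
            pick(reference_ct, "neurite"), pick(reference_ct, "soma"))
  if (!all(is.finite(vals))) stop("Ct values must be finite")
  ddct <- (vals[1] - vals[3]) - (vals[2] - vals[4])
  list(ddct = ddct, relative_expression = 2^(-ddct))
}
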