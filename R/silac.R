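# Label-swap SILAC ratio aggregation. Forward = H neurites + M soma (H/M),
# reverse = M neurites + H soma (M/H); both ratios estimate the same
# neurite/soma quantity, so averaging them in log space cancels labeling
# bias without the upward bias an arithmetic mean of raw ratios carries.

#' Aggregate forward/reverse label-swap ratio tables
#'
#' Outer-joins the two experiments on \code{protein_id} and averages the
#' available log2 ratios. Proteins quantified in only one experiment are
#' retained with \code{n_experiments = 1}. Non-positive ratios are rejected
#' (reported via attribute \code{"rejected"}).
#'
#' @param fw,rev data.frames with columns \code{protein_id} and
#'   \code{ratio} (H/M for forward, M/H for reverse).
#' @return data.frame: \code{protein_id}, \code{ratio_fw}, \code{ratio_rev},
#'   \code{avg_log2}, \code{n_experiments}.
#' @examples
#' labelswapAggregate(data.frame(protein_id = "p1", ratio = 2),
#'                    data.frame(protein_id = "p1", ratio = 8))
#' @export
labelswapAggregate <- function(fw, rev) {
  clean <- function(d, label) {
    stopifnot(all(c("protein_id", "ratio") %in% names(d)))
    bad <- !is.na(d$ratio) & d$ratio <= 0
    if (any(bad))
      warning(sum(bad), " non-positive ratio(s) rejected in ", label,
              " table")
    d[!bad, c("protein_id", "ratio")]
  }
  fw <- clean(fw, "forward"); rev <- clean(rev, "reverse")
  m <- merge(fw, rev, by = "protein_id", all = TRUE,
             suffixes = c("_fw", "_rev"))
  l2 <- cbind(log2(m$ratio_fw), log2(m$ratio_rev))
  out <- data.frame(protein_id = m$protein_id,
                    ratio_fw = m$ratio_fw, ratio_rev = m$ratio_rev,
                    avg_log2 = rowMeans(l2, na.rm = TRUE),
                    n_experiments = rowSums(!is.na(l2)),
                    stringsAsFactors = FALSE)
  out[out$n_experiments > 0, , drop = FALSE]
}

#' Correlate label-swap translation rates with Ribo-seq enrichment
#'
#' @param ratios output of [labelswapAggregate()].
#' @param ribo_records enrichment data.frame (e.g. from
#'   [translationEnrichment()]) with \code{feature_id} and \code{log2fc}.
#' @return list(\code{r}, \code{pvalue}, \code{n}) from
#'   [crossLayerCorrelation()].
#' @export
compareToRiboseq <- function(ratios, ribo_records) {
  a <- data.frame(feature_id = ratios$protein_id, log2fc = ratios$avg_log2,
                  stringsAsFactors = FALSE)
  crossLayerCorrelation(a, ribo_records)
}

#' Proteins above a fold-change threshold
#'
#' Selects proteins whose average ratio strictly exceeds \code{fold} — the
#' construction used to pick proteins upregulated upon neuronal
#' differentiation (iNeuron/mESC ratio > 4).
#'
#' @param ratios output of [labelswapAggregate()].
#' @param fold linear fold-change cutoff (strict).
#' @return character vector of protein ids.
#' @export
thresholdUpregulated <- function(ratios, fold = 4) {
  ratios$protein_id[2^ratios$avg_log2 > fold]
}
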