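# Footprint QC and CDS-level translation quantification. Coordinates are
# transcript-relative, 0-based; the CDS occupies [0, cds_length) and the
# frame of the CDS start is 0.

#' Footprint length filter
#'
#' Retains footprints in the gel-selected size range (default 27-30 nt) and
#' reports retention statistics via attribute \code{"retention"}.
#'
#' @param table footprint data.frame with at least \code{length}.
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered table; \code{attr(, "retention")} holds
#'   \code{n_in}, \code{n_retained}, \code{fraction}.
#' @export
filterFootprints <- function(table, min_len = 27L, max_len = 30L) {
  stopifnot(min_len <= max_len, min_len > 0)
  keep <- table$length >= min_len & table$length <= max_len
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- list(n_in = nrow(table), n_retained = sum(keep),
                                 fraction = if (nrow(table)) mean(keep)
                                            else NA_real_)
  out
}

#' P-site frame periodicity profile
#'
#' Shifts every footprint 5' end by the P-site offset (default +12 nt, the
#' standard correction for ~29-mers), takes the position modulo 3, and
#' tabulates frames per read length and pooled. The hallmark of genuine
#' translation is a strong excess of frame 0; departure from the uniform
#' frame distribution is scored by a chi-square goodness-of-fit test
#' (df = 2).
#'
#' @param table filtered footprint data.frame (\code{gene_id},
#'   \code{five_prime_offset}, \code{length}).
#' @param offset_nt P-site offset added to the 5' end (>= 0).
#' @param cds_lengths optional named vector; records whose gene is absent
#'   are skipped and reported in \code{n_skipped}.
#' @return list: \code{counts} (length x frame matrix), \code{pooled}
#'   (frame counts), \code{frame0_fraction} per length,
#'   \code{pooled_frame0_fraction}, \code{chi2_p} per length,
#'   \code{pooled_chi2_p}, \code{n_skipped}.
#' @export
frameProfile <- function(table, offset_nt = 12L, cds_lengths = NULL) {
  stopifnot(offset_nt >= 0)
  n_skipped <- 0L
  if (!is.null(cds_lengths)) {
    known <- table$gene_id %in% names(cds_lengths)
    n_skipped <- sum(!known)
    table <- table[known, , drop = FALSE]
  }
  if (nrow(table) == 0)
    return(list(counts = matrix(0L, 0, 3,
                                dimnames = list(NULL, paste0("frame", 0:2))),
                pooled = setNames(rep(0L, 3), paste0("frame", 0:2)),
                frame0_fraction = numeric(), pooled_frame0_fraction = NA_real_,
                chi2_p = numeric(), pooled_chi2_p = NA_real_,
                n_skipped = n_skipped))
  frame <- (table$five_prime_offset + offset_nt) %% 3L
  lens <- sort(unique(table$length))
  counts <- t(vapply(lens, function(L)
    tabulate(frame[table$length == L] + 1L, 3L), integer(3)))
  dimnames(counts) <- list(as.character(lens), paste0("frame", 0:2))
  pooled <- colSums(counts)
  gof <- function(x) {
    n <- sum(x)
    if (n == 0) return(NA_real_)
    stat <- sum((x - n / 3)^2 / (n / 3))
    pchisq(stat, df = 2, lower.tail = FALSE)
  }
  list(counts = counts,
       pooled = pooled,
       frame0_fraction = counts[, 1] / pmax(rowSums(counts), 1),
       pooled_frame0_fraction = pooled[1] / sum(pooled),
       chi2_p = apply(counts, 1, gof),
       pooled_chi2_p = gof(pooled),
       n_skipped = n_skipped)
}

#' CDS-level footprint quantification (RPKM)
#'
#' Counts P-sites (5' end + offset) falling inside the half-open CDS
#' interval [0, cds_length) per gene and sample, then normalizes to RPKM
#' with CDS lengths via [computeRpkm()]. Footprints whose P-site lands in
#' the 5' UTR or beyond the stop are not counted.
#'
#' @param table filtered footprint data.frame with \code{gene_id},
#'   \code{five_prime_offset}, \code{compartment}, \code{replicate}.
#' @param cds_lengths named vector of CDS lengths (nt) for every gene in
#'   the table.
#' @param offset_nt P-site offset (default 12).
#' @return [CompartmentMatrix-class] of kind \code{"rpkm"} over CDS.
#' @export
cdsQuantify <- function(table, cds_lengths, offset_nt = 12L) {
  miss <- setdiff(unique(table$gene_id), names(cds_lengths))
  if (length(miss))
    stop("missing cds_length for: ", paste(head(miss, 10), collapse = ", "))
  if (any(cds_lengths <= 0)) stop("cds_lengths must be > 0")
  genes <- names(cds_lengths)
  psite <- table$five_prime_offset + offset_nt
  in_cds <- psite >= 0 & psite < cds_lengths[table$gene_id]
  tab <- table[in_cds, , drop = FALSE]
  sample_label <- paste(tab$compartment, tab$replicate, sep = "_")
  reps <- sort(unique(table$replicate))
  labels <- c(paste0("soma_", reps), paste0("neurite_", reps))
  cnt <- matrix(0L, length(genes), length(labels),
                dimnames = list(genes, labels))
  xt <- base::table(factor(tab$gene_id, genes), factor(sample_label, labels))
  cnt[] <- as.integer(xt)
  computeRpkm(CompartmentMatrix(cnt, kind = "counts"), cds_lengths)
}

#' Translation enrichment and locally-translated calls
#'
#' Delegates to [compartmentEnrichment()] on the CDS RPKM matrix and flags
#' transcripts translated at least twofold more in neurites
#' (\code{log2fc > 1} and \code{p < 0.05} by default).
#'
#' @param cds_rpkm [CompartmentMatrix-class] from [cdsQuantify()].
#' @param fc_thresh,p_thresh thresholds for the locally-translated flag.
#' @param ... passed to [compartmentEnrichment()].
#' @return enrichment data.frame with an extra logical column
#'   \code{locally_translated}.
#' @export
translationEnrichment <- function(cds_rpkm, fc_thresh = 1.0,
                                  p_thresh = 0.05, ...) {
  rec <- compartmentEnrichment(cds_rpkm, ...)
  rec <- classifyLocalized(rec, fc_thresh = fc_thresh, p_thresh = p_thresh)
  rec$locally_translated <- rec$call == "neurite"
  rec
}
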