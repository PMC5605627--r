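#' RPKM normalization
#'
#' Reads per kilobase of feature per million mapped reads:
#' \code{RPKM[f, s] = counts[f, s] / ((length_f / 1000) * (colsum_s / 1e6))}.
#' The per-library denominator is the total of counted features, so each
#' column satisfies the conservation identity
#' \code{sum_f RPKM[f, s] * length_f / 1000 = 1e6}.
#'
#' @param counts [CompartmentMatrix-class] of kind \code{"counts"}.
#' @param lengths named numeric vector of feature lengths in nt; every
#'   counted feature must be present with a positive length.
#' @return [CompartmentMatrix-class] of kind \code{"rpkm"}.
#' @examples
#' m <- matrix(c(90, 10), 2, 2, dimnames = list(c("A", "B"),
#'                                              c("soma_1", "neurite_1")))
#' computeRpkm(CompartmentMatrix(m, kind = "counts"),
#'             c(A = 900, B = 100))
#' @export
computeRpkm <- function(counts, lengths) {
  stopifnot(is(counts, "CompartmentMatrix"))
  v <- abundances(counts)
  miss <- setdiff(rownames(v), names(lengths)[!is.na(lengths)])
  if (length(miss))
    stop("no length for counted feature(s): ",
         paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
  len <- lengths[rownames(v)]
  if (any(len <= 0)) stop("feature lengths must be > 0")
  libsize <- colSums(v)
  if (any(libsize <= 0)) stop("library size must be > 0 in every sample")
  rpkm <- sweep(v / (len / 1000), 2, libsize / 1e6, "/")
  CompartmentMatrix(rpkm, compartment = compartments(counts),
                    replicate = SummarizedExperiment::colData(counts)$replicate,
                    kind = "rpkm")
}

#' Expression-threshold detection per compartment
#'
#' A feature counts as detected in a compartment when its mean RPKM across
#' that compartment's replicates strictly exceeds its biotype's threshold:
#' by default > 1 RPKM for protein-coding genes and > 10 RPKM for lncRNAs.
#'
#' @param rpkm [CompartmentMatrix-class] of kind \code{"rpkm"}.
#' @param biotype named character vector (\code{"coding"} / \code{"lncRNA"})
#'   covering every feature.
#' @param coding_thresh,lnc_thresh strict detection thresholds in RPKM.
#' @return list with character vectors \code{soma} and \code{neurite} of
#'   detected feature ids.
#' @export
filterExpressed <- function(rpkm, biotype, coding_thresh = 1,
                            lnc_thresh = 10) {
  stopifnot(is(rpkm, "CompartmentMatrix"))
  ids <- rownames(rpkm)
  unknown <- setdiff(ids, names(biotype))
  if (length(unknown))
    stop("unknown biotype for: ", paste(head(unknown, 10), collapse = ", "))
  bt <- biotype[ids]
  if (!all(bt %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'")
  thr <- ifelse(bt == "coding", coding_thresh, lnc_thresh)
  detect <- function(comp) {
    if (length(ids) == 0) return(character())
    ids[compartmentMeans(rpkm, comp) > thr]
  }
  list(soma = detect("soma"), neurite = detect("neurite"))
}

#' Down-shifted Gaussian imputation of missing log2 intensities
#'
#' The field-standard treatment of missing-not-at-random label-free
#' proteomics values: each missing cell in sample column s is drawn from
#' \code{Normal(mu_s - shift * sd_s, width * sd_s)}, where \code{mu_s} and
#' \code{sd_s} are the mean and SD of that column's observed values — i.e.
#' draws from the low tail where undetected proteins are presumed to live.
#' Observed cells are never touched.
#'
#' @param x [CompartmentMatrix-class] of kind \code{"log2intensity"}.
#' @param shift,width down-shift and width in multiples of the column SD
#'   (defaults 1.8 and 0.3).
#' @param seed integer seed making the draws reproducible.
#' @param scope which missing cells to impute. \code{"all"}: every missing
#'   cell. \code{"compartment"}: only gene-compartment blocks with no
#'   observed value at all — the proteins "detected in only one
#'   compartment". \code{"group"}: blocks with fewer than 2 observed
#'   values (a single replicate cannot form a variance); blocks with >= 2
#'   observed keep their sporadic missing cells missing, so partially
#'   observed groups are never contaminated with low draws.
#' @return list with \code{matrix} (a [CompartmentMatrix-class], complete
#'   under \code{scope = "all"}) and \code{mask}, a data.frame of
#'   (feature_id, sample_label) naming every imputed cell.
#' @export
imputeMissing <- function(x, shift = 1.8, width = 0.3, seed = 1L,
                          scope = c("all", "compartment", "group")) {
  stopifnot(is(x, "CompartmentMatrix"), shift > 0, width > 0)
  scope <- match.arg(scope)
  v <- abundances(x)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(v)[n_obs < 2], collapse = ", "))
  target <- is.na(v)
  if (scope != "all") {
    min_obs <- if (scope == "compartment") 1L else 2L
    comp <- compartments(x)
    for (cp in c("soma", "neurite")) {
      cols <- comp == cp
      undersampled <- rowSums(!is.na(v[, cols, drop = FALSE])) < min_obs
      target[!undersampled, cols] <- FALSE
    }
  }
  out <- v
  .with_stream(as.integer(seed), "impute", {
    for (j in seq_len(ncol(v))) {
      nas <- which(target[, j])
      if (!length(nas)) next
      mu <- mean(v[, j], na.rm = TRUE)
      sd_j <- stats::sd(v[, j], na.rm = TRUE)
      out[nas, j] <- rnorm(length(nas), mu - shift * sd_j, width * sd_j)
    }
  })
  nas <- which(target, arr.ind = TRUE)
  mask <- data.frame(feature_id = rownames(v)[nas[, 1]],
                     sample_label = colnames(v)[nas[, 2]],
                     stringsAsFactors = FALSE)
  cm <- CompartmentMatrix(out, compartment = compartments(x),
                          replicate = SummarizedExperiment::colData(x)$replicate,
                          kind = "log2intensity")
  list(matrix = cm, mask = mask)
}
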