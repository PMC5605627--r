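#' Construct a CompartmentMatrix
#'
#' @param values numeric matrix, features in rows. Row names are the feature
#'   ids. Column order must match \code{compartment}/\code{replicate}.
#' @param compartment character vector, one of \code{"soma"}/\code{"neurite"}
#'   per column. If \code{NULL}, parsed from column names of the form
#'   \code{soma_1, ..., neurite_R}.
#' @param replicate integer replicate index per column (parsed from column
#'   names when \code{NULL}).
#' @param kind measurement scale: \code{"counts"}, \code{"rpkm"} or
#'   \code{"log2intensity"}.
#' @return A [CompartmentMatrix-class].
#' @examples
#' m <- matrix(rpois(12, 50), 2,
#'             dimnames = list(c("g1", "g2"),
#'                             c(paste0("soma_", 1:3), paste0("neurite_", 1:3))))
#' cm <- CompartmentMatrix(m, kind = "counts")
#' compartments(cm)
#' @export
CompartmentMatrix <- function(values, compartment = NULL, replicate = NULL,
                              kind = c("counts", "rpkm", "log2intensity")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(compartment)) {
    if (is.null(colnames(values)))
      stop("supply 'compartment' or name columns as <compartment>_<rep>")
    compartment <- sub("_[0-9]+$", "", colnames(values))
  }
  if (is.null(replicate)) {
    replicate <- if (!is.null(colnames(values)) &&
                     all(grepl("_[0-9]+$", colnames(values))))
      as.integer(sub("^.*_", "", colnames(values)))
    else as.integer(stats::ave(seq_along(compartment), compartment,
                               FUN = seq_along))
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste(compartment, replicate, sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(compartment = compartment,
                                   replicate = as.integer(replicate),
                                   row.names = colnames(values)))
  new("CompartmentMatrix", se, kind = kind)
}

#' @describeIn CompartmentMatrix compartment label of each sample.
#' @param x a CompartmentMatrix.
#' @export
compartments <- function(x) SummarizedExperiment::colData(x)$compartment

#' @describeIn CompartmentMatrix measurement scale of the assay.
#' @export
assayKind <- function(x) x@kind

#' @describeIn CompartmentMatrix the abundance matrix.
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' Per-feature means within one compartment
#'
#' @param x a [CompartmentMatrix-class].
#' @param compartment \code{"soma"} or \code{"neurite"}.
#' @param na.rm drop missing cells (relevant for log2 intensities).
#' @return named numeric vector of row means over the compartment's
#'   replicates.
#' @export
compartmentMeans <- function(x, compartment = c("soma", "neurite"),
                             na.rm = FALSE) {
  compartment <- match.arg(compartment)
  rowMeans(abundances(x)[, compartments(x) == compartment, drop = FALSE],
           na.rm = na.rm)
}

setMethod("show", "CompartmentMatrix", function(object) {
  v <- abundances(object)
  cat(sprintf("CompartmentMatrix [%s]: %d features x %d samples (%d soma, %d neurite)\n",
              object@kind, nrow(v), ncol(v),
              sum(compartments(object) == "soma"),
              sum(compartments(object) == "neurite")))
  if (anyNA(v))
    cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
                100 * mean(is.na(v))))
})

setMethod("show", "SimBundle", function(object) {
  cat(sprintf("SimBundle: %d genes (%d coding), %d replicates/compartment\n",
              nrow(object@truth),
              sum(object@truth$biotype == "coding"),
              object@config@n_replicates))
  cat(sprintf("  footprints: %d records; silac: %d proteins\n",
              nrow(object@footprints), nrow(object@silac)))
  cat("  mechanisms:\n")
  print(table(object@truth$mechanism))
})

#' Read / write a compartment matrix as TSV
#'
#' The layout is one header line \code{feature_id, soma_1..soma_R,
#' neurite_1..neurite_R} and one row per feature; empty cells denote
#' missing values (log2-intensity matrices only).
#'
#' @param path file path.
#' @param kind measurement scale, see [CompartmentMatrix()].
#' @return `readCompartmentMatrix`: a [CompartmentMatrix-class];
#'   `writeCompartmentMatrix`: invisibly, `path`.
#' @export
readCompartmentMatrix <- function(path,
                                  kind = c("counts", "rpkm",
                                           "log2intensity")) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  CompartmentMatrix(m, kind = match.arg(kind))
}

#' @rdname readCompartmentMatrix
#' @param x a [CompartmentMatrix-class].
#' @export
writeCompartmentMatrix <- function(x, path) {
  d <- data.frame(feature_id = rownames(x), abundances(x),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
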