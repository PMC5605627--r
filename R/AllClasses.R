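#' @import methods
#' @importFrom stats rnbinom rpois rnorm runif rbinom plogis pt pchisq
#'   p.adjust var cor dhyper setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

.MECHANISMS <- c("mrna_localization", "intermediate", "protein_transport",
                 "local_translation", "combination", "soma_restricted",
                 "unlocalized")

.ASSAY_KINDS <- c("counts", "rpkm", "log2intensity")

#' Compartmentalized abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay of
#' feature-by-sample abundances, where every sample is annotated with a
#' cellular compartment (\code{"soma"} or \code{"neurite"}) and a replicate
#' index. The \code{kind} slot records the measurement scale: raw read
#' counts, RPKM, or log2 intensities (the only kind in which missing cells
#' are tolerated, as is typical for label-free proteomics).
#'
#' @slot kind character(1); one of \code{"counts"}, \code{"rpkm"},
#'   \code{"log2intensity"}.
#' @export
setClass("CompartmentMatrix",
         contains = "SummarizedExperiment",
         slots = c(kind = "character"))

setValidity("CompartmentMatrix", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("compartment", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'compartment' and 'replicate'")
  else {
    if (!all(cd$compartment %in% c("soma", "neurite")))
      msg <- c(msg, "compartment must be 'soma' or 'neurite'")
    if (!all(table(factor(cd$compartment,
                          c("soma", "neurite"))) >= 1L))
      msg <- c(msg, "need at least one sample per compartment")
  }
  if (length(object@kind) != 1L || !object@kind %in% .ASSAY_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.ASSAY_KINDS, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature ids")
  v <- SummarizedExperiment::assay(object)
  if (identical(object@kind, "counts")) {
    if (anyNA(v)) msg <- c(msg, "counts may not contain NA")
    else if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (identical(object@kind, "rpkm") && !anyNA(v) && any(v < 0))
    msg <- c(msg, "rpkm values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic compartmentalized multi-omics generator.
#' Constructed with [SimConfig()]; all generative settings live here so a
#' bundle is fully reproducible from the configuration alone.
#'
#' @slot n_genes,n_replicates integer counts.
#' @slot mechanism_fractions named numeric summing to 1 over the mechanism
#'   taxonomy.
#' @slot rna_depth,footprint_depth expected reads/footprints per library.
#' @slot frame0_bias probability mass on the translated frame, in [1/3, 1].
#' @slot loc_effect_log2 true |log2 fold change| given to localized features.
#' @slot protein_noise_sd replicate noise SD of log2 protein intensities.
#' @slot rna_dispersion negative-binomial dispersion of RNA counts.
#' @slot missing_steepness,missing_midpoint logistic missingness curve
#'   parameters (log2-intensity units).
#' @slot silac_noise_sd,silac_coverage label-swap ratio noise SD (log2) and
#'   fraction of proteins quantified.
#' @slot lnc_fraction fraction of genes drawn as lncRNA.
#' @slot circ_fraction fraction of genes flagged neurite-preferential for
#'   the circular/linear generator.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
         slots = c(n_genes = "integer",
                   n_replicates = "integer",
                   mechanism_fractions = "numeric",
                   rna_depth = "numeric",
                   footprint_depth = "numeric",
                   frame0_bias = "numeric",
                   loc_effect_log2 = "numeric",
                   protein_noise_sd = "numeric",
                   rna_dispersion = "numeric",
                   missing_steepness = "numeric",
                   missing_midpoint = "numeric",
                   silac_noise_sd = "numeric",
                   silac_coverage = "numeric",
                   lnc_fraction = "numeric",
                   circ_fraction = "numeric",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  f <- object@mechanism_fractions
  if (is.null(names(f)) || !all(names(f) %in% .MECHANISMS))
    msg <- c(msg, sprintf("mechanism_fractions names must be in {%s}",
                          paste(.MECHANISMS, collapse = ", ")))
  if (any(f < 0)) msg <- c(msg, "mechanism fractions must be >= 0")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "mechanism_fractions must sum to 1 (tolerance 1e-9)")
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be >= 1")
  if (object@n_replicates < 2L) msg <- c(msg, "n_replicates must be >= 2")
  if (object@frame0_bias < 1 / 3 || object@frame0_bias > 1)
    msg <- c(msg, "frame0_bias must lie in [1/3, 1]")
  if (object@rna_dispersion < 0) msg <- c(msg, "rna_dispersion must be >= 0")
  if (object@rna_depth < 0 || object@footprint_depth < 0)
    msg <- c(msg, "library depths must be >= 0")
  if (object@silac_coverage < 0 || object@silac_coverage > 1)
    msg <- c(msg, "silac_coverage must lie in [0, 1]")
  if (object@lnc_fraction < 0 || object@lnc_fraction >= 1)
    msg <- c(msg, "lnc_fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-omics bundle
#'
#' Container for one simulated experiment: the ground-truth gene table
#' (identity, biotype, lengths, mechanism and the three true log2 fold
#' changes), plus every observable table the analysis consumes. Truth is
#' kept separate from observables so recovery can be scored honestly.
#'
#' @slot truth data.frame of ground-truth genes.
#' @slot rna,protein,circ,linear [CompartmentMatrix] objects (protein with
#'   MNAR missing cells; circ/linear are back-splice / linear junction
#'   counts).
#' @slot footprints data.frame of ribosome footprint records.
#' @slot silac data.frame of forward/reverse label-swap ratios.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("SimBundle",
         slots = c(truth = "data.frame",
                   rna = "CompartmentMatrix",
                   footprints = "data.frame",
                   protein = "CompartmentMatrix",
                   silac = "data.frame",
                   circ = "CompartmentMatrix",
                   linear = "CompartmentMatrix",
                   config = "SimConfig"))

setValidity("SimBundle", function(object) {
  ids <- object@truth$gene_id
  bad <- function(x) length(x) && !all(x %in% ids)
  msg <- character()
  if (bad(rownames(object@rna))) msg <- c(msg, "rna keyed off-annotation")
  if (bad(object@footprints$gene_id))
    msg <- c(msg, "footprints keyed off-annotation")
  if (bad(rownames(object@protein)))
    msg <- c(msg, "protein keyed off-annotation")
  if (bad(object@silac$protein_id)) msg <- c(msg, "silac keyed off-annotation")
  if (length(msg)) msg else TRUE
})
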