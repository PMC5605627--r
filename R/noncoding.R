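# lncRNA localization and circular-vs-linear transcript preference.

#' Neurite-enriched lncRNAs
#'
#' A lncRNA makes the set when it is detected in at least one compartment
#' above the lncRNA threshold (> 10 RPKM by default, via
#' [filterExpressed()]) and its enrichment call is \code{"neurite"}
#' (twofold, p < 0.05).
#'
#' @param rpkm [CompartmentMatrix-class] of kind \code{"rpkm"}.
#' @param records enrichment data.frame with \code{feature_id} and
#'   \code{call}.
#' @param biotype named biotype vector covering the matrix features.
#' @param ... passed to [filterExpressed()].
#' @return character vector of neurite-enriched lncRNA ids.
#' @export
lncrnaLocalization <- function(rpkm, records, biotype, ...) {
  detected <- filterExpressed(rpkm, biotype, ...)
  lnc <- names(biotype)[biotype == "lncRNA"]
  localized <- records$feature_id[records$call == "neurite"]
  intersect(intersect(lnc, union(detected$soma, detected$neurite)),
            localized)
}

#' Circular-to-linear junction ratios per compartment
#'
#' Junction counts are depth-normalized to counts per million within the
#' circular and linear tables separately, averaged over replicates per
#' compartment, and compared as
#' \code{log2((circ + pc) / (linear + pc))} in each compartment.
#' A gene present in only one table contributes zero counts to the other
#' and is flagged \code{single_table}.
#'
#' @param circ,linear [CompartmentMatrix-class] junction count matrices.
#' @param pseudocount added to both normalized abundances (> 0).
#' @return data.frame: \code{gene_id}, replicate-mean CPM per isoform and
#'   compartment (\code{circ_neurite}, \code{circ_soma},
#'   \code{linear_neurite}, \code{linear_soma}), \code{log2_cl_neurite},
#'   \code{log2_cl_soma}, \code{single_table}, and \code{circ_class} from
#'   [classifyCirc()].
#' @export
circLinearRatio <- function(circ, linear, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  cpm_means <- function(x) {
    v <- abundances(x)
    libs <- colSums(v)
    cpm <- sweep(v, 2, ifelse(libs > 0, libs, 1) / 1e6, "/")
    list(neurite = rowMeans(cpm[, compartments(x) == "neurite",
                                drop = FALSE]),
         soma = rowMeans(cpm[, compartments(x) == "soma", drop = FALSE]))
  }
  cc <- cpm_means(circ); ll <- cpm_means(linear)
  ids <- union(rownames(circ), rownames(linear))
  get <- function(m, comp) {
    out <- setNames(numeric(length(ids)), ids)
    out[names(m[[comp]])] <- m[[comp]]
    out
  }
  cn <- get(cc, "neurite"); cs <- get(cc, "soma")
  ln <- get(ll, "neurite"); ls <- get(ll, "soma")
  rec <- data.frame(gene_id = ids,
                    circ_neurite = cn, circ_soma = cs,
                    linear_neurite = ln, linear_soma = ls,
                    log2_cl_neurite = log2((cn + pseudocount) /
                                           (ln + pseudocount)),
                    log2_cl_soma = log2((cs + pseudocount) /
                                        (ls + pseudocount)),
                    single_table = !(ids %in% rownames(circ)) |
                                   !(ids %in% rownames(linear)),
                    stringsAsFactors = FALSE, row.names = NULL)
  classifyCirc(rec)
}

#' Classify circular-transcript compartment preference
#'
#' \code{neurite_preferential_circ}: circular isoform at least twice the
#' linear one in neurites while the soma ratio leans linear
#' (\code{log2_cl_neurite > 1} and \code{log2_cl_soma < 0}) — the Ephb2
#' pattern. \code{circ_enriched_elsewhere}: neurite circ excess without the
#' soma reversal (\code{log2_cl_neurite > 1} only). Everything else:
#' \code{none}. The first class is by construction a subset of genes
#' satisfying the second class's neurite condition.
#'
#' @param records data.frame with \code{log2_cl_neurite},
#'   \code{log2_cl_soma}.
#' @return `records` with the \code{circ_class} column (re)computed.
#' @export
classifyCirc <- function(records) {
  cls <- rep("none", nrow(records))
  neur <- records$log2_cl_neurite > 1
  cls[neur] <- "circ_enriched_elsewhere"
  cls[neur & records$log2_cl_soma < 0] <- "neurite_preferential_circ"
  records$circ_class <- cls
  records
}
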