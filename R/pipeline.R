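#' Run the full localization analysis on a multi-omics bundle
#'
#' Convenience driver chaining the whole pipeline: RPKM normalization and
#' detection filtering of the RNA layer, imputation and enrichment of the
#' protein layer, footprint filtering / frame QC / CDS quantification of
#' the Ribo-seq layer, label-swap aggregation of the SILAC layer,
#' lncRNA and circular-RNA calls, and mechanism attribution with the
#' summary report.
#'
#' @param bundle a [SimBundle-class] (or any object with the same slots).
#' @param impute_seed seed for the imputation draws.
#' @param psite_offset P-site offset in nt for the Ribo-seq layer.
#' @return list with elements \code{rna_rpkm}, \code{detected},
#'   \code{rna_enrichment}, \code{protein_enrichment}, \code{impute_mask},
#'   \code{frame_qc}, \code{ribo_enrichment}, \code{silac},
#'   \code{silac_vs_ribo}, \code{lncrna_neurite}, \code{circ},
#'   \code{mechanism_calls}, \code{summary}.
#' @examples
#' b <- simulateBundle(SimConfig(n_genes = 150, rna_depth = 5e4,
#'                               footprint_depth = 5e4, seed = 2))
#' res <- analyzeBundle(b)
#' res$summary$fractions
#' @export
analyzeBundle <- function(bundle, impute_seed = 1L, psite_offset = 12L) {
  truth <- bundle@truth
  tx_len <- setNames(truth$tx_length, truth$gene_id)
  biotype <- setNames(truth$biotype, truth$gene_id)
  coding <- truth[truth$biotype == "coding", ]
  cds_len <- setNames(coding$cds_length, coding$gene_id)

  rna_rpkm <- computeRpkm(bundle@rna, tx_len)
  detected <- filterExpressed(rna_rpkm, biotype)
  rna_enrich <- compartmentEnrichment(rna_rpkm)

  imp <- imputeMissing(bundle@protein, seed = impute_seed,
                       scope = "group")
  prot_enrich <- compartmentEnrichment(imp$matrix)

  fp <- filterFootprints(bundle@footprints)
  frame_qc <- frameProfile(fp, offset_nt = psite_offset,
                           cds_lengths = cds_len)
  ribo_enrich <- if (nrow(fp) > 0) {
    translationEnrichment(cdsQuantify(fp, cds_len,
                                      offset_nt = psite_offset))
  } else NULL

  silac <- labelswapAggregate(
    data.frame(protein_id = bundle@silac$protein_id,
               ratio = bundle@silac$ratio_fw),
    data.frame(protein_id = bundle@silac$protein_id,
               ratio = bundle@silac$ratio_rev))
  silac_vs_ribo <- if (nrow(silac) >= 3 && !is.null(ribo_enrich))
    tryCatch(compareToRiboseq(silac, ribo_enrich), error = function(e) NULL)
    else NULL

  lnc <- lncrnaLocalization(rna_rpkm, rna_enrich, biotype)
  circ <- circLinearRatio(bundle@circ, bundle@linear)

  calls <- callMechanism(prot_enrich, rna_enrich, ribo_enrich)
  summary <- summarizeMechanisms(calls, rna_records = rna_enrich)

  list(rna_rpkm = rna_rpkm, detected = detected,
       rna_enrichment = rna_enrich, protein_enrichment = prot_enrich,
       impute_mask = imp$mask, frame_qc = frame_qc,
       ribo_enrichment = ribo_enrich, silac = silac,
       silac_vs_ribo = silac_vs_ribo, lncrna_neurite = lnc, circ = circ,
       mechanism_calls = calls, summary = summary)
}
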