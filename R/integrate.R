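# Mechanism attribution: explain each neurite-localized protein by the
# behavior of its mRNA and its local translation.

.CATEGORIES <- c("mrna_localization", "intermediate", "protein_transport",
                 "local_translation", "combination", "unquantified")

#' Attribute protein localization to a mechanism
#'
#' For every protein record, combines the RNA and Ribo-seq enrichment of
#' the encoding gene into one of five mechanism categories (plus
#' \code{unquantified} and \code{not_neurite_localized}), by a strict
#' decision tree:
#' \enumerate{
#'   \item protein not neurite-localized (call != "neurite") ->
#'     \code{not_neurite_localized};
#'   \item RNA log2FC > 1 with RNA p < 0.05 -> \code{mrna_localization};
#'   \item RNA log2FC in (0, 1) -> \code{intermediate};
#'   \item RNA log2FC < 0: Ribo log2FC < 0 -> \code{protein_transport};
#'     Ribo log2FC > 1 -> \code{local_translation}; Ribo log2FC in (0, 1)
#'     -> \code{combination}.
#' }
#' Tie rules for the measure-zero boundaries finite data can hit: RNA
#' log2FC exactly 0 (or exactly 1 without significance, or > 1 without
#' significance) falls to \code{intermediate}; Ribo log2FC exactly 0 or 1
#' falls to \code{combination}. A gene missing its RNA record — or missing
#' its Ribo record when the tree needs it — is \code{unquantified}, never
#' silently dropped.
#'
#' @param protein_records enrichment data.frame for the proteome
#'   (\code{feature_id}, \code{log2fc}, \code{pvalue}, \code{call});
#'   required.
#' @param rna_records,ribo_records enrichment data.frames for RNA-seq and
#'   Ribo-seq; genes may be absent.
#' @return data.frame: \code{gene_id}, the three log2FCs and the
#'   protein/RNA p-values, and \code{category}.
#' @export
callMechanism <- function(protein_records, rna_records, ribo_records) {
  if (is.null(protein_records) || nrow(protein_records) == 0)
    stop("protein records are required")
  idx <- function(rec) match(protein_records$feature_id, rec$feature_id)
  ir <- idx(rna_records); ib <- idx(ribo_records)
  rna_fc <- rna_records$log2fc[ir]; rna_p <- rna_records$pvalue[ir]
  ribo_fc <- ribo_records$log2fc[ib]

  n <- nrow(protein_records)
  cat <- rep("unquantified", n)
  loc <- protein_records$call == "neurite"
  cat[!loc] <- "not_neurite_localized"

  has_rna <- !is.na(rna_fc)
  mrna <- loc & has_rna & rna_fc > 1 & rna_p < 0.05
  inter <- loc & has_rna & !mrna & rna_fc >= 0
  rna_neg <- loc & has_rna & rna_fc < 0
  has_ribo <- !is.na(ribo_fc)
  cat[mrna] <- "mrna_localization"
  cat[inter] <- "intermediate"
  cat[rna_neg & has_ribo & ribo_fc < 0] <- "protein_transport"
  cat[rna_neg & has_ribo & ribo_fc > 1] <- "local_translation"
  cat[rna_neg & has_ribo & ribo_fc >= 0 & ribo_fc <= 1] <- "combination"
  # loc & (!has_rna | (rna_neg & !has_ribo)) remain "unquantified"

  data.frame(gene_id = protein_records$feature_id,
             protein_log2fc = protein_records$log2fc,
             protein_p = protein_records$pvalue,
             rna_log2fc = rna_fc, rna_p = rna_p,
             ribo_log2fc = ribo_fc,
             category = cat,
             stringsAsFactors = FALSE)
}

#' Summarize mechanism attribution
#'
#' Counts and fractions per category over the neurite-localized proteins,
#' the RNA-protein cross-layer Pearson correlation, and the mean Ribo-seq
#' log2FC per category (the boxplot statistic of the three-way split).
#'
#' @param calls output of [callMechanism()].
#' @param rna_records,ribo_records optional enrichment tables used for the
#'   cross-layer correlation (computed against the protein columns already
#'   in `calls`).
#' @return list: \code{n_localized_total}, named \code{counts} and
#'   \code{fractions} over the localized categories (fractions are NaN with
#'   a warning when nothing is localized), \code{mean_ribo_log2fc} per
#'   category, and \code{rna_protein_pearson} (NULL unless `rna_records`
#'   given).
#' @export
summarizeMechanisms <- function(calls, rna_records = NULL,
                                ribo_records = NULL) {
  loc <- calls[calls$category != "not_neurite_localized", , drop = FALSE]
  counts <- setNames(integer(length(.CATEGORIES)), .CATEGORIES)
  tab <- base::table(loc$category)
  counts[names(tab)] <- as.integer(tab)
  n_total <- sum(counts)
  if (n_total == 0) {
    warning("no neurite-localized proteins; fractions undefined")
    fractions <- counts * NaN
  } else fractions <- counts / n_total
  mean_ribo <- vapply(split(loc$ribo_log2fc, factor(loc$category,
                                                    .CATEGORIES)),
                      function(x) mean(x, na.rm = TRUE), numeric(1))
  pearson <- NULL
  if (!is.null(rna_records)) {
    prot <- data.frame(feature_id = calls$gene_id,
                       log2fc = calls$protein_log2fc,
                       stringsAsFactors = FALSE)
    pearson <- crossLayerCorrelation(prot, rna_records)
  }
  list(n_localized_total = n_total, counts = counts, fractions = fractions,
       mean_ribo_log2fc = mean_ribo, rna_protein_pearson = pearson)
}

#' Overlay an RNA-binding-protein census on the localized proteome
#'
#' Intersects the neurite-localized proteins with a curated census of
#' mRNA-binding proteins and returns their enrichment records.
#'
#' @param protein_records enrichment data.frame with \code{call}.
#' @param census character vector of RBP identifiers (non-empty).
#' @return the subset of `protein_records` that are RBPs with
#'   \code{call == "neurite"}.
#' @export
rbpOverlay <- function(protein_records, census) {
  if (length(census) == 0) stop("census must be non-empty")
  out <- protein_records[protein_records$call == "neurite" &
                           protein_records$feature_id %in% census, ,
                         drop = FALSE]
  rownames(out) <- NULL
  out
}
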