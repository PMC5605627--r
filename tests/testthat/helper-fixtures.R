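# Small builders shared across tests. Everything is generated in code; no
# fixture files.

cm <- function(soma, neurite, kind = "rpkm", ids = NULL) {
  soma <- as.matrix(soma); neurite <- as.matrix(neurite)
  m <- cbind(soma, neurite)
  colnames(m) <- c(paste0("soma_", seq_len(ncol(soma))),
                   paste0("neurite_", seq_len(ncol(neurite))))
  rownames(m) <- if (is.null(ids)) paste0("g", seq_len(nrow(m))) else ids
  CompartmentMatrix(m, kind = kind)
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 200L, rna_depth = 5e4, footprint_depth = 5e4,
                   seed = 11L)
  do.call(SimConfig, utils::modifyList(defaults, args))
}

enrich_rec <- function(ids, log2fc, pvalue = rep(0.01, length(ids))) {
  classifyLocalized(data.frame(feature_id = ids, log2fc = log2fc,
                               pvalue = pvalue, stringsAsFactors = FALSE))
}
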