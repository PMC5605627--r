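# 2x2 set-association machinery (motif hits, modification sites) and a
# position-weight-matrix scanner producing the hit tables it consumes.

#' Fisher's exact test for a 2x2 table
#'
#' Rows are set membership (in / out), columns hit status (hit / no hit).
#' The two-sided p-value follows the probability-mass rule: with margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed one (a relative
#' tolerance of 1e-7 guards against ties lost to rounding). The odds ratio
#' is the sample cross-product ratio \code{(a d) / (b c)} — not the
#' conditional MLE some implementations report — with the convention
#' \code{Inf} when \code{b c = 0} while \code{a d > 0}, and \code{NaN} when
#' both products vanish.
#'
#' @param a,b,c,d non-negative integer cell counts: \code{a} = in-set hits,
#'   \code{b} = in-set non-hits, \code{c} = out-of-set hits, \code{d} =
#'   out-of-set non-hits.
#' @return list(\code{odds_ratio}, \code{pvalue}).
#' @examples
#' fisherExact2x2(3, 1, 1, 3) # p = 34/70
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  n <- sum(cells)
  if (n == 0) stop("empty table")
  odds <- if (b * c > 0) (a * d) / (b * c)
          else if (a * d > 0) Inf
          else NaN
  m <- a + b          # in-set margin
  k <- a + c          # hit margin
  support <- max(0, k - (n - m)):min(k, m)
  probs <- dhyper(support, m, n - m, k)
  p_obs <- dhyper(a, m, n - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds, pvalue = min(p, 1))
}

#' Foreground and reference gene sets for motif association
#'
#' Joins RNA and protein enrichment records on \code{feature_id} and builds
#' the three disjoint sets used in motif/modification association:
#' \describe{
#'   \item{foreground}{localized to neurites and translated there: RNA and
#'     protein log2FC > 1, both p < 0.05.}
#'   \item{reference_soma}{enriched and translated in soma: RNA and protein
#'     log2FC < -1, both p < 0.05.}
#'   \item{reference_unlocalized}{equally distributed: both log2FCs within
#'     (-0.58, 0.58), i.e. less than 1.5-fold either way.}
#' }
#'
#' @param rna_records,protein_records enrichment data.frames with
#'   \code{feature_id}, \code{log2fc}, \code{pvalue}.
#' @return list of three disjoint character vectors: \code{foreground},
#'   \code{reference_soma}, \code{reference_unlocalized}.
#' @export
defineGeneSets <- function(rna_records, protein_records) {
  m <- merge(rna_records[, c("feature_id", "log2fc", "pvalue")],
             protein_records[, c("feature_id", "log2fc", "pvalue")],
             by = "feature_id", suffixes = c("_rna", "_prot"))
  fg <- m$log2fc_rna > 1 & m$pvalue_rna < 0.05 &
        m$log2fc_prot > 1 & m$pvalue_prot < 0.05
  soma <- m$log2fc_rna < -1 & m$pvalue_rna < 0.05 &
          m$log2fc_prot < -1 & m$pvalue_prot < 0.05
  unloc <- abs(m$log2fc_rna) < 0.58 & abs(m$log2fc_prot) < 0.58
  list(foreground = m$feature_id[fg],
       reference_soma = m$feature_id[soma & !fg],
       reference_unlocalized = m$feature_id[unloc & !fg & !soma])
}

#' Scan sequences with a position weight matrix
#'
#' Scores every length-\code{width} window of each sequence as the sum of
#' per-position log2-odds (PWM probabilities against the background) and
#' reports the maximum; a sequence is a hit when its maximum reaches
#' \code{threshold}. Sequences shorter than the motif get \code{NA} scores
#' and a \code{too_short} flag instead of a hit.
#'
#' @param sequences named character vector over A/C/G/U (T accepted and
#'   treated as U).
#' @param pwm 4 x width numeric matrix of per-position log2-odds weights,
#'   rows named A, C, G, U (build one from position probabilities with
#'   [pwmFromProbs()]).
#' @param threshold minimum max-window score for a hit.
#' @return data.frame: \code{id}, \code{max_score}, \code{hit},
#'   \code{too_short}.
#' @export
scanPwm <- function(sequences, pwm, threshold) {
  stopifnot(length(sequences) > 0, nrow(pwm) == 4, ncol(pwm) >= 1)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "U")
  lodds <- pwm[c("A", "C", "G", "U"), , drop = FALSE]
  w <- ncol(pwm)
  ids <- if (is.null(names(sequences))) paste0("seq", seq_along(sequences))
         else names(sequences)
  score1 <- function(s, id) {
    chars <- strsplit(toupper(chartr("T", "U", s)), "")[[1]]
    code <- match(chars, c("A", "C", "G", "U"))
    if (anyNA(code))
      stop(sprintf("invalid character '%s' in sequence '%s' at position %d",
                   chars[which(is.na(code))[1]], id, which(is.na(code))[1]))
    L <- length(code)
    if (L < w) return(NA_real_)
    max(vapply(seq_len(L - w + 1L), function(i)
      sum(lodds[cbind(code[i:(i + w - 1L)], seq_len(w))]), numeric(1)))
  }
  ms <- mapply(score1, sequences, ids)
  data.frame(id = ids, max_score = unname(ms),
             hit = !is.na(ms) & ms >= threshold,
             too_short = is.na(ms),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Log2-odds weights from position probabilities
#'
#' @param probs 4 x width matrix of position probabilities (columns sum
#'   to 1), rows named A, C, G, U.
#' @param background length-4 background distribution (sums to 1; default
#'   uniform 0.25).
#' @return 4 x width log2-odds weight matrix for [scanPwm()].
#' @export
pwmFromProbs <- function(probs, background = rep(0.25, 4)) {
  stopifnot(nrow(probs) == 4, abs(sum(background) - 1) < 1e-9)
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "U")
  log2(probs) - log2(background)
}

#' Set-versus-set hit association
#'
#' Builds the 2x2 contingency table (set membership x hit status) from a
#' hit table and two disjoint gene sets and tests it with
#' [fisherExact2x2()].
#'
#' @param hits data.frame with \code{id} and logical \code{hit} covering
#'   every member of both sets.
#' @param set_a,set_b disjoint, non-empty character vectors.
#' @return list(\code{table} — named a/b/c/d counts, \code{odds_ratio},
#'   \code{pvalue}).
#' @export
setAssociation <- function(hits, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("both sets must be non-empty")
  if (length(intersect(set_a, set_b)))
    stop("sets overlap: ", paste(head(intersect(set_a, set_b), 5),
                                 collapse = ", "))
  missing <- setdiff(c(set_a, set_b), hits$id)
  if (length(missing))
    stop("no hit record for: ", paste(head(missing, 10), collapse = ", "))
  h <- setNames(hits$hit, hits$id)
  a <- sum(h[set_a]); b <- sum(!h[set_a])
  cc <- sum(h[set_b]); d <- sum(!h[set_b])
  res <- fisherExact2x2(a, b, cc, d)
  list(table = c(a = a, b = b, c = cc, d = d),
       odds_ratio = res$odds_ratio, pvalue = res$pvalue)
}
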