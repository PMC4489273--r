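#' Hypergeometric tail probability
#'
#' Probability of drawing `x` or more marked items when `N` items are drawn
#' without replacement from a universe of `M` items of which `k` are marked.
#' `mode = "at_least"` (default) is the standard enrichment tail
#' P(X >= x); `mode = "exclusive"` is the strictly-greater tail
#' P(X > x) = 1 - CDF(x), a convention that appears in parts of the
#' enrichment literature; it excludes the observed count itself and is
#' never larger than the inclusive tail.
#'
#' @param x observed overlap, `0 <= x <= min(k, N)`.
#' @param k number of marked items in the universe.
#' @param N number of draws (query-set size).
#' @param M universe size, `M >= max(k, N)`.
#' @param mode `"at_least"` (P(X >= x)) or `"exclusive"` (P(X > x)).
#' @return probability in \[0, 1\].
#' @export
hypergeom_pvalue <- function(x, k, N, M, mode = c("at_least", "exclusive")) {
  mode <- match.arg(mode)
  if (any(c(x, k, N, M) < 0) || x > min(k, N) || k > M || N > M)
    stop("hypergeometric bounds violated: need 0 <= x <= min(k, N) and k, N <= M")
  q <- if (mode == "at_least") x - 1 else x
  stats::phyper(q, m = k, n = M - k, k = N, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; order-preserving,
#' monotone, capped at 1.  Ties resolve deterministically (stable on input
#' order).
#'
#' @param pvalues numeric vector of raw P-values in \[0, 1\].
#' @return adjusted P-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a query set against annotation terms
#'
#' One hypergeometric test per term (term sets restricted to the universe),
#' BH adjustment across all terms, significant hits sorted by adjusted
#' P-value.
#'
#' @param query_set query entity IDs; must be a subset of `universe`.
#' @param annotations an [annotation_table()].
#' @param universe background entity IDs.
#' @param alpha adjusted-P cutoff for the returned rows (default 0.05).
#' @param all return every tested term instead of only significant ones.
#' @return data frame with columns term_id, term_name, x, k, N, M, p_raw,
#'   p_adjusted.
#' @export
ora <- function(query_set, annotations, universe, alpha = 0.05, all = FALSE) {
  stopifnot(inherits(annotations, "annotation_table"))
  query_set <- unique(query_set)
  universe <- unique(universe)
  offenders <- setdiff(query_set, universe)
  if (length(offenders))
    stop("query IDs outside the universe: ",
         paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) ", ...")
  M <- length(universe)
  N <- length(query_set)
  res <- do.call(rbind, lapply(names(annotations$terms), function(tid) {
    tset <- intersect(annotations$terms[[tid]], universe)
    data.frame(term_id = tid,
               term_name = unname(annotations$term_names[[tid]]),
               x = length(intersect(tset, query_set)),
               k = length(tset), N = N, M = M,
               stringsAsFactors = FALSE)
  }))
  res$p_raw <- mapply(hypergeom_pvalue, x = res$x, k = res$k,
                      MoreArgs = list(N = N, M = M))
  res$p_adjusted <- bh_adjust(res$p_raw)
  res <- res[order(res$p_adjusted, res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  if (all) res else res[res$p_adjusted < alpha, , drop = FALSE]
}
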