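#' Pairwise functional similarity of a gene set
#'
#' Scores every unordered pair of genes by the similarity of their
#' annotation-term sets.  The default measure is the Jaccard index of the
#' term sets; `"weighted_jaccard"` weights each term by its information
#' content, -log of the fraction of annotated genes carrying it, so that
#' sharing a rare term counts for more than sharing a ubiquitous one (and
#' scores are nearly tie-free).  Any function
#' `f(terms1, terms2) -> [0, 1]` can be plugged in instead, e.g. a
#' semantic-similarity measure computed over an ontology graph.  Genes
#' without annotations are dropped with a warning.
#'
#' @param genes character vector of gene IDs (>= 2 annotated ones).
#' @param annotations an [annotation_table()].
#' @param measure `"jaccard"`, `"weighted_jaccard"`, or a function of two
#'   term-ID vectors.
#' @return numeric vector of length `choose(n, 2)` with names
#'   `"gene1|gene2"`.
#' @export
pairwise_similarity <- function(genes, annotations, measure = "jaccard") {
  g2t <- entity_terms(annotations)
  genes <- unique(genes)
  annotated <- genes[genes %in% names(g2t)]
  if (length(annotated) < length(genes))
    warning("dropping ", length(genes) - length(annotated),
            " unannotated gene(s)")
  if (length(annotated) < 2L)
    stop("need at least 2 annotated genes to form pairs")
  fun <- if (is.function(measure)) measure else switch(
    measure,
    jaccard = function(a, b) length(intersect(a, b)) / length(union(a, b)),
    weighted_jaccard = {
      ic <- -log(lengths(annotations$terms) / length(g2t))
      ic <- pmax(ic, .Machine$double.eps)  # ubiquitous terms keep weight > 0
      function(a, b)
        sum(ic[intersect(a, b)]) / sum(ic[union(a, b)])
    },
    stop("unknown similarity measure '", measure, "'"))
  pairs <- combn(sort(annotated), 2L)
  scores <- apply(pairs, 2L, function(p) fun(g2t[[p[1]]], g2t[[p[2]]]))
  setNames(as.numeric(scores), paste(pairs[1, ], pairs[2, ], sep = "|"))
}

#' Permutation null distribution of pairwise similarities
#'
#' Repeatedly samples `n_genes` genes without replacement from the
#' annotated universe, scores all their pairs, and pools the scores over
#' all permutations.
#'
#' @param n_genes genes per permutation sample.
#' @param annotations an [annotation_table()].
#' @param universe background gene IDs (default: all annotated genes).
#' @param n_permutations number of permutation rounds (default 1000).
#' @param seed optional RNG seed.
#' @param measure see [pairwise_similarity()].
#' @return numeric vector of pooled null similarity scores.
#' @export
permutation_null <- function(n_genes, annotations, universe = NULL,
                             n_permutations = 1000, seed = NULL,
                             measure = "jaccard") {
  stopifnot(n_permutations >= 1)
  g2t <- entity_terms(annotations)
  if (is.null(universe)) universe <- names(g2t)
  universe <- intersect(unique(universe), names(g2t))
  if (n_genes > length(universe))
    stop("n_genes (", n_genes, ") exceeds the annotated universe (",
         length(universe), ")")
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(seq_len(n_permutations), function(i) {
    smp <- sample(universe, n_genes)
    unname(suppressWarnings(pairwise_similarity(smp, annotations, measure)))
  }), use.names = FALSE)
}

#' One-sided Kolmogorov-Smirnov homogeneity test
#'
#' Tests whether the observed similarity scores are stochastically greater
#' than the null scores (alternative: the observed CDF lies below the null
#' CDF).
#'
#' @param observed observed pairwise similarity scores (non-empty).
#' @param null null (permutation) scores (non-empty).
#' @return list with `ks_statistic` and `ks_p`.
#' @export
ks_homogeneity_test <- function(observed, null) {
  if (!length(observed) || !length(null))
    stop("observed and null score vectors must be non-empty")
  kt <- suppressWarnings(stats::ks.test(observed, null,
                                        alternative = "less", exact = FALSE))
  list(ks_statistic = unname(kt$statistic), ks_p = unname(kt$p.value))
}

#' Functional homogeneity of a TF-miRNA pair's gene set
#'
#' Scores the pairwise similarity of the genes co-targeted by (or, in
#' `co_regulated` mode, regulated by either of) a TF-miRNA pair, builds a
#' permutation null of equal-size random gene sets from the annotated
#' universe, and applies the one-sided KS test.
#'
#' @param net a [reg_network()] containing the pair.
#' @param tf,mirna the pair's node IDs.
#' @param annotations an [annotation_table()].
#' @param mode `"co_targeted"` (shared target genes only, default) or
#'   `"co_regulated"` (union of the TF's and the miRNA's target genes).
#' @param n_permutations permutation rounds (default 1000).
#' @param seed optional RNG seed.
#' @param universe background gene IDs (default: all annotated genes).
#' @param measure see [pairwise_similarity()].
#' @return object of class `homogeneity_result`.
#' @export
homogeneity_test <- function(net, tf, mirna, annotations,
                             mode = c("co_targeted", "co_regulated"),
                             n_permutations = 1000, seed = NULL,
                             universe = NULL, measure = "jaccard") {
  mode <- match.arg(mode)
  ed <- network_edges(net)
  tft <- tf_gene_targets(ed)[[tf]]
  mirt <- mirna_gene_targets(ed)[[mirna]]
  genes <- if (mode == "co_targeted") intersect(tft, mirt)
           else union(tft, mirt)
  genes <- setdiff(genes, c(tf, mirna))
  if (length(genes) < 2L)
    stop("pair (", tf, ", ", mirna, ") has fewer than 2 ", mode, " genes")
  observed <- pairwise_similarity(genes, annotations, measure)
  g2t <- entity_terms(annotations)
  n_used <- sum(genes %in% names(g2t))
  null <- permutation_null(n_used, annotations, universe = universe,
                           n_permutations = n_permutations, seed = seed,
                           measure = measure)
  kt <- ks_homogeneity_test(observed, null)
  structure(list(tf = tf, mirna = mirna, mode = mode, genes = genes,
                 observed_scores = observed, null_scores = null,
                 n_permutations = n_permutations,
                 ks_statistic = kt$ks_statistic, ks_p = kt$ks_p,
                 seed = seed),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf(paste0("Functional homogeneity of (%s, %s), %s genes (n = %d)\n",
                     "  median similarity: observed %.3f vs null %.3f\n",
                     "  one-sided KS: D = %.3f, P = %.3g (%d permutations)\n"),
              x$tf, x$mirna, x$mode, length(x$genes),
              stats::median(x$observed_scores), stats::median(x$null_scores),
              x$ks_statistic, x$ks_p, x$n_permutations))
  invisible(x)
}
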