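MOTIF_TYPES <- c("coreg_FFL", "TF_FFL", "miRNA_FFL", "composite_FFL")

# target maps used by the pair test and the motif scan
tf_gene_targets <- function(ed) {
  sub <- ed[ed$interaction_type == "TF2gene", , drop = FALSE]
  lapply(split(sub$to, sub$from), unique)
}
mirna_gene_targets <- function(ed) {
  sub <- ed[ed$interaction_type == "miRNA2gene", , drop = FALSE]
  lapply(split(sub$to, sub$from), unique)
}

#' Significant co-regulating TF-miRNA pairs
#'
#' Tests every (TF, miRNA) pair sharing at least one target gene for a
#' larger-than-chance number of common targets, with a hypergeometric test:
#' k = miRNA target-gene count, N = TF-regulated gene count, x = common
#' target count, and M = the number of genes in the union of all
#' miRNA-targeted and all TF-regulated genes in the network.  P-values are
#' BH-adjusted across all tested pairs.
#'
#' @param net a [reg_network()] containing TF2gene and miRNA2gene edges.
#' @param alpha adjusted-P cutoff for significance (default 0.05).
#' @param mode tail convention, see [hypergeom_pvalue()].
#' @param all return all tested pairs (with a `significant` flag) instead
#'   of only the significant ones.
#' @return data frame with columns tf, mirna, k, N, x, M, p_raw,
#'   p_adjusted, significant.
#' @export
significant_pairs <- function(net, alpha = 0.05, mode = "at_least",
                              all = FALSE) {
  ed <- network_edges(net)
  tf_t <- tf_gene_targets(ed)
  mir_t <- mirna_gene_targets(ed)
  empty <- data.frame(tf = character(0), mirna = character(0),
                      k = integer(0), N = integer(0), x = integer(0),
                      M = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(tf_t) || !length(mir_t)) {
    warning("network has no TF2gene or no miRNA2gene edges; no pairs tested")
    return(empty)
  }
  M <- length(unique(c(unlist(tf_t, use.names = FALSE),
                       unlist(mir_t, use.names = FALSE))))
  rows <- list()
  for (tf in names(tf_t)) {
    for (mir in names(mir_t)) {
      x <- length(intersect(tf_t[[tf]], mir_t[[mir]]))
      if (x == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, mirna = mir,
        k = length(mir_t[[mir]]), N = length(tf_t[[tf]]), x = x, M = M,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no TF-miRNA pair shares a target gene")
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$p_raw <- mapply(hypergeom_pvalue, x = res$x, k = res$k, N = res$N,
                      MoreArgs = list(M = M, mode = mode))
  res$p_adjusted <- bh_adjust(res$p_raw)
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_adjusted, res$p_raw, res$tf, res$mirna), ,
             drop = FALSE]
  rownames(res) <- NULL
  if (all) res else res[res$significant, , drop = FALSE]
}

#' Enumerate TF-miRNA-gene feed-forward-loop motifs
#'
#' For each significant TF-miRNA pair and each of their common target
#' genes, the triple is classified by the regulation between TF and miRNA:
#' no edge in either direction gives a co-regulation FFL; a TF -> miRNA
#' edge alone a TF-FFL; a miRNA -> TF edge alone a miRNA-FFL; both edges a
#' composite FFL.  The four classes are exclusive and exhaustive, so every
#' co-targeting triple maps to exactly one class.
#'
#' @param net a [reg_network()].
#' @param pairs data frame of pairs as returned by [significant_pairs()];
#'   defaults to the significant pairs of `net` at `alpha`.
#' @param alpha cutoff used when `pairs` is not supplied.
#' @return data frame with columns motif_type, tf, mirna, gene.
#' @export
find_ffl_motifs <- function(net, pairs = NULL, alpha = 0.05) {
  if (is.null(pairs)) pairs <- significant_pairs(net, alpha = alpha)
  ed <- network_edges(net)
  tf_t <- tf_gene_targets(ed)
  mir_t <- mirna_gene_targets(ed)
  t2m <- ed[ed$interaction_type == "TF2miRNA", , drop = FALSE]
  nodes <- network_nodes(net)$name
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    tf <- pairs$tf[i]; mir <- pairs$mirna[i]
    if (!(tf %in% nodes) || !(mir %in% nodes))
      stop("pair (", tf, ", ", mir, ") not present in the network")
    shared <- setdiff(intersect(tf_t[[tf]], mir_t[[mir]]), c(tf, mir))
    if (!length(shared)) next
    tf2mir <- any(t2m$from == tf & t2m$to == mir)
    mir2tf <- tf %in% mir_t[[mir]]
    type <- if (tf2mir && mir2tf) "composite_FFL"
            else if (tf2mir) "TF_FFL"
            else if (mir2tf) "miRNA_FFL"
            else "coreg_FFL"
    out[[length(out) + 1L]] <- data.frame(motif_type = type, tf = tf,
                                          mirna = mir, gene = shared,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(motif_type = character(0), tf = character(0),
                      mirna = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count motifs per type
#'
#' @param motifs data frame from [find_ffl_motifs()].
#' @return named integer vector over the four motif classes.
#' @export
count_motifs <- function(motifs) {
  tab <- table(factor(motifs$motif_type, levels = MOTIF_TYPES))
  setNames(as.integer(tab), MOTIF_TYPES)
}

#' Degree-preserving network randomization
#'
#' Edge-swap randomization: repeatedly two edges (v1, v2) and (v3, v4) are
#' chosen at random and rewired to (v1, v4) and (v3, v2), provided neither
#' replacement edge already exists and no self-loop would arise.  Swaps are
#' stratified by interaction type (a TF2gene edge only swaps with another
#' TF2gene edge), which preserves per-node, per-type in- and out-degrees
#' and node classes exactly — an unstratified swap could create an edge
#' no interaction type permits.  `swaps_per_edge * L` swap attempts are
#' made in total for a network of L edges (default 2 x L); failed attempts
#' are skipped but still counted.
#'
#' @param net a [reg_network()] with at least 2 edges.
#' @param swaps_per_edge attempted swaps per edge (default 2).
#' @param seed optional RNG seed.
#' @return a randomized [reg_network()] on the same vertex set.
#' @export
degree_preserving_randomize <- function(net, swaps_per_edge = 2, seed = NULL) {
  stopifnot(igraph::ecount(net) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ed <- network_edges(net)
  nd <- network_nodes(net)
  for (tp in unique(ed$interaction_type)) {
    idx <- which(ed$interaction_type == tp)
    Ls <- length(idx)
    if (Ls < 2L) next
    from <- ed$from[idx]; to <- ed$to[idx]
    keys <- paste(from, to, sep = "\r")
    n_steps <- ceiling(swaps_per_edge * Ls)
    for (s in seq_len(n_steps)) {
      ij <- sample.int(Ls, 2L)
      v1 <- from[ij[1]]; v2 <- to[ij[1]]
      v3 <- from[ij[2]]; v4 <- to[ij[2]]
      if (v1 == v3 || v2 == v4) next          # swap is a no-op
      if (v1 == v4 || v3 == v2) next          # would create a self-loop
      k3 <- paste(v1, v4, sep = "\r"); k4 <- paste(v3, v2, sep = "\r")
      if (k3 %in% keys || k4 %in% keys) next  # replacement edge exists
      to[ij[1]] <- v4; to[ij[2]] <- v2
      keys[ij] <- c(k3, k4)
    }
    ed$from[idx] <- from; ed$to[idx] <- to
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
  as_reg_network(g)
}

#' Motif randomization summary statistics
#'
#' `motif_zscore` is the standardized excess of the observed motif count
#' over the randomized mean, (N_o - N_m) / sigma, `NA` when sigma is 0;
#' `motif_empirical_p` is the raw empirical tail N_h / N_r, the fraction of
#' random networks whose count reaches the observed one.
#'
#' @param N_o observed motif count.
#' @param N_m mean count over random networks.
#' @param sigma standard deviation of random counts.
#' @param N_h number of random networks with count >= N_o.
#' @param N_r number of random networks.
#' @return numeric vector.
#' @export
motif_zscore <- function(N_o, N_m, sigma) {
  ifelse(sigma > 0, (N_o - N_m) / sigma, NA_real_)
}

#' @rdname motif_zscore
#' @export
motif_empirical_p <- function(N_h, N_r) {
  stopifnot(N_r >= 1)
  N_h / N_r
}

#' Motif significance against degree-preserving random networks
#'
#' Counts each motif type in the real network (N_o) and in `n_networks`
#' degree-preserving randomizations.  Per type it reports the random mean
#' N_m and standard deviation sigma, the Z-score (N_o - N_m) / sigma, the
#' number N_h of random networks reaching at least N_o, the raw empirical
#' P-value N_h / N_r (which can be 0 at finite N_r) and its add-one
#' smoothed companion (N_h + 1) / (N_r + 1).  By default the real
#' network's significant pairs are frozen and their co-targeting triples
#' are re-counted on each randomized replica, which yields a comparable,
#' non-degenerate null; with `recompute_pairs = TRUE` the pair test is
#' instead re-run per replica at the same `alpha` — under that convention
#' the BH prefilter leaves almost no significant pair on a randomized
#' network, so null counts collapse to zero and sigma degenerates.
#'
#' @param net a [reg_network()].
#' @param alpha significance cutoff for pairs (default 0.05).
#' @param n_networks number of randomizations N_r (default 100).
#' @param swaps_per_edge see [degree_preserving_randomize()].
#' @param seed optional RNG seed; fixing it makes the report reproducible.
#' @param recompute_pairs recompute significant pairs per replica instead
#'   of freezing the real network's pairs (default FALSE).
#' @return data frame of class `motif_significance` with one row per motif
#'   type: N_o, N_m, sigma, zscore, N_h, N_r, empirical_p, empirical_p_smoothed.
#' @export
motif_significance <- function(net, alpha = 0.05, n_networks = 100,
                               swaps_per_edge = 2, seed = NULL,
                               recompute_pairs = FALSE) {
  if (n_networks < 1L) stop("n_networks must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pairs_obs <- significant_pairs(net, alpha = alpha)
  N_o <- count_motifs(find_ffl_motifs(net, pairs_obs))
  counts <- matrix(0L, nrow = length(MOTIF_TYPES), ncol = n_networks,
                   dimnames = list(MOTIF_TYPES, NULL))
  for (r in seq_len(n_networks)) {
    rnet <- degree_preserving_randomize(net, swaps_per_edge)
    rpairs <- if (recompute_pairs)
      suppressWarnings(significant_pairs(rnet, alpha = alpha)) else pairs_obs
    counts[, r] <- count_motifs(suppressWarnings(
      find_ffl_motifs(rnet, rpairs)))
  }
  N_m <- rowMeans(counts)
  sigma <- apply(counts, 1, stats::sd)
  N_h <- rowSums(counts >= N_o)
  res <- data.frame(motif_type = MOTIF_TYPES, N_o = unname(N_o),
                    N_m = unname(N_m), sigma = unname(sigma),
                    zscore = unname(motif_zscore(N_o, N_m, sigma)),
                    N_h = unname(N_h), N_r = n_networks,
                    empirical_p = unname(motif_empirical_p(N_h, n_networks)),
                    empirical_p_smoothed = (unname(N_h) + 1) / (n_networks + 1),
                    stringsAsFactors = FALSE)
  attr(res, "config") <- list(alpha = alpha, n_networks = n_networks,
                              swaps_per_edge = swaps_per_edge, seed = seed,
                              recompute_pairs = recompute_pairs)
  class(res) <- c("motif_significance", "data.frame")
  res
}

#' @export
print.motif_significance <- function(x, ...) {
  cat("Motif significance (", x$N_r[1], " random networks)\n", sep = "")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
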