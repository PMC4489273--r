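# Fixture builders and independent oracles shared across the suite.

# write a small interaction TSV and return its path
write_tsv_fixture <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  hdr <- "regulator\ttarget\tinteraction_type\tevidence\tsource"
  writeLines(c(if (header) hdr, lines), path)
  path
}

# small deterministic interaction records data frame
toy_records <- function() {
  data.frame(
    regulator = c("TF1", "TF1", "TF2", "hsa-mir-1", "hsa-mir-1", "hsa-mir-2"),
    target = c("G1", "hsa-mir-1", "G2", "G1", "G2", "hsa-mir-1"),
    interaction_type = c("TF2gene", "TF2miRNA", "TF2gene",
                         "miRNA2gene", "miRNA2gene", "miRNA2miRNA"),
    evidence = c("validated", "validated", "predicted",
                 "validated", "predicted", "predicted"),
    source = "toy", stringsAsFactors = FALSE)
}

# random typed records over small node pools; densities chosen so that
# triples of every motif class arise by chance
random_records <- function(n_tf = 4, n_gene = 8, n_mir = 4,
                           p = c(TF2gene = 0.35, TF2miRNA = 0.3,
                                 miRNA2gene = 0.35, miRNA2miRNA = 0.15)) {
  tfs <- paste0("TF", seq_len(n_tf))
  genes <- paste0("G", seq_len(n_gene))
  mirs <- paste0("hsa-mir-", seq_len(n_mir))
  grid <- function(r, t, tp, pr) {
    g <- expand.grid(regulator = r, target = t, stringsAsFactors = FALSE)
    g <- g[g$regulator != g$target & stats::runif(nrow(g)) < pr, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    cbind(g, interaction_type = tp, evidence = "validated", source = "rand",
          stringsAsFactors = FALSE)
  }
  rec <- rbind(grid(tfs, genes, "TF2gene", p[["TF2gene"]]),
               grid(tfs, mirs, "TF2miRNA", p[["TF2miRNA"]]),
               grid(mirs, c(genes, tfs), "miRNA2gene", p[["miRNA2gene"]]),
               grid(mirs, mirs, "miRNA2miRNA", p[["miRNA2miRNA"]]))
  rec
}

random_network <- function(...) {
  rec <- random_records(...)
  if (is.null(rec) || nrow(rec) == 0L) return(NULL)
  reg_network(rec)
}

# ---- independent oracles ------------------------------------------------

# exact hypergeometric upper tail by summing point masses
oracle_hyper_tail <- function(x, k, N, M, inclusive = TRUE) {
  lo <- if (inclusive) x else x + 1
  hi <- min(k, N)
  if (lo > hi) return(0)
  sum(choose(k, lo:hi) * choose(M - k, N - (lo:hi))) / choose(M, N)
}

# BH step-up computed from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive minimum dominating set size over all subsets (n <= ~15)
oracle_mds_size <- function(adj_list, closed = TRUE) {
  n <- length(adj_list)
  cover <- lapply(seq_len(n), function(v)
    if (closed) c(v, adj_list[[v]]) else adj_list[[v]])
  best <- n + 1L
  for (mask in 0:(2^n - 1)) {
    chosen <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(chosen) >= best) next
    if (all(seq_len(n) %in% unlist(cover[chosen])))
      best <- length(chosen)
  }
  best
}

# brute-force enumeration of classified co-targeting triples over all
# (tf, mirna, gene) combinations restricted to a pair list
oracle_triples <- function(net, pairs) {
  ed <- network_edges(net)
  has <- function(from, to, tp)
    any(ed$from == from & ed$to == to & ed$interaction_type == tp)
  nd <- network_nodes(net)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    tf <- pairs$tf[i]; mir <- pairs$mirna[i]
    for (g in setdiff(nd$name, c(tf, mir))) {
      if (!has(tf, g, "TF2gene") || !has(mir, g, "miRNA2gene")) next
      t2m <- has(tf, mir, "TF2miRNA")
      m2t <- has(mir, tf, "miRNA2gene")
      type <- if (t2m && m2t) "composite_FFL" else if (t2m) "TF_FFL"
              else if (m2t) "miRNA_FFL" else "coreg_FFL"
      out[[length(out) + 1L]] <- data.frame(motif_type = type, tf = tf,
                                            mirna = mir, gene = g,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif_type = character(0), tf = character(0),
                      mirna = character(0), gene = character(0)))
  do.call(rbind, out)
}

sort_df <- function(df) {
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# small undirected random graph as a reg_network-compatible igraph
random_undirected <- function(n, p) {
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- paste0("N", seq_len(n))
  igraph::V(g)$node_class <- "gene"
  g
}

# annotation fixture with independently assigned terms (structureless)
random_annotations <- function(n_genes = 200, terms_per_gene = 15,
                               n_terms = 80, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- paste0("T", seq_len(n_terms))
  genes <- paste0("G", seq_len(n_genes))
  g2t <- setNames(lapply(genes, function(g) sample(vocab, terms_per_gene)),
                  genes)
  annotation_table(split(rep(names(g2t), lengths(g2t)),
                         unlist(g2t, use.names = FALSE)))
}
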