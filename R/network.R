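#' Build a regulatory network from interaction records
#'
#' A regulatory network is a directed igraph whose vertices carry a
#' `node_class` attribute (`TF` / `gene` / `miRNA`) and whose edges carry
#' `interaction_type` and `evidence`.  A node is classed as a TF iff it acts
#' as regulator in any TF2gene or TF2miRNA record of the loaded database
#' (TFs are otherwise ordinary genes); miRNA class follows from the typed
#' endpoints.  Self-loops are dropped (with a warning) since no interaction
#' type permits self-regulation in this model.
#'
#' @param records data frame of interaction records (as in the `records`
#'   element of an [interaction_db()]).
#' @param tf_ids optional character vector of known TF IDs (defaults to the
#'   TF-role regulators found in `records`); pass the full database's TF set
#'   when building a subnetwork so that classification does not depend on
#'   which edges survived filtering.
#' @return igraph object of class `c("reg_network", "igraph")`.
#' @export
reg_network <- function(records, tf_ids = NULL) {
  if (!all(c("regulator_class", "target_class") %in% names(records))) {
    cls <- do.call(rbind, TYPE_CLASSES[records$interaction_type])
    records$regulator_class <- if (nrow(records)) cls[, "regulator"] else character(0)
    records$target_class <- if (nrow(records)) cls[, "target"] else character(0)
  }
  loops <- records$regulator == records$target
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop record(s)")
    records <- records[!loops, , drop = FALSE]
  }
  if (is.null(tf_ids))
    tf_ids <- unique(records$regulator[records$regulator_class == "TF"])

  ids <- unique(c(records$regulator, records$target))
  mir <- unique(c(records$regulator[records$regulator_class == "miRNA"],
                  records$target[records$target_class == "miRNA"]))
  node_class <- ifelse(ids %in% mir, "miRNA",
                       ifelse(ids %in% tf_ids, "TF", "gene"))
  g <- igraph::graph_from_data_frame(
    d = records[, c("regulator", "target", "interaction_type", "evidence"),
                drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = ids, node_class = node_class,
                          stringsAsFactors = FALSE))
  class(g) <- unique(c("reg_network", class(g)))
  g
}

as_reg_network <- function(g) {
  class(g) <- unique(c("reg_network", class(g)))
  g
}

#' @export
print.reg_network <- function(x, ...) {
  cls <- table(factor(igraph::V(x)$node_class, levels = c("TF", "gene", "miRNA")))
  cat(sprintf("Regulatory network: %d nodes (%d TF, %d gene, %d miRNA), %d edges\n",
              igraph::vcount(x), cls[["TF"]], cls[["gene"]], cls[["miRNA"]],
              igraph::ecount(x)))
  tab <- table(factor(igraph::E(x)$interaction_type, levels = INTERACTION_TYPES))
  for (tp in INTERACTION_TYPES)
    if (tab[[tp]] > 0) cat(sprintf("  %-12s %d\n", tp, tab[[tp]]))
  invisible(x)
}

#' Extract the edge table of a regulatory network
#'
#' @param net a [reg_network()].
#' @return data frame with columns from, to, interaction_type, evidence.
#' @export
network_edges <- function(net) {
  igraph::as_data_frame(net, what = "edges")
}

network_nodes <- function(net) {
  igraph::as_data_frame(net, what = "vertices")
}

#' Write a regulatory network to disk
#'
#' `edge_tsv` writes an edge table plus a `<path>.nodes.tsv` sidecar with
#' node classes; `graphml` writes a single GraphML file.  Both formats
#' round-trip exactly through [read_network()].
#'
#' @param net a [reg_network()].
#' @param path output file.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (igraph::ecount(net) == 0L)
    warning("writing an empty network to ", path)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(network_nodes(net), paste0(path, ".nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' @param path file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return a [reg_network()].
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if ("id" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "id")  # reader artifact
    return(as_reg_network(g))
  }
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  nd <- utils::read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE,
                          colClasses = "character")
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
  as_reg_network(g)
}

#' Build the combined co-regulatory network
#'
#' Pools all four interaction types: an edge of the database enters the
#' network iff both its endpoints are deregulated (gene-class endpoints must
#' be in `genes`, miRNA-class endpoints in `mirnas`).  Isolated nodes are
#' never included.
#'
#' @param db an [interaction_db()].
#' @param genes deregulated gene/TF IDs (non-empty).
#' @param mirnas deregulated miRNA IDs (may be empty; use [infer_mirnas()]
#'   first when only genes are available).
#' @return a [reg_network()]; empty (with a warning) when no edge qualifies.
#' @export
build_combined_network <- function(db, genes, mirnas = character()) {
  stopifnot(inherits(db, "interaction_db"), length(genes) > 0L)
  rec <- db$records
  in_set <- function(id, cls) {
    ifelse(cls == "miRNA", id %in% mirnas, id %in% genes)
  }
  keep <- in_set(rec$regulator, rec$regulator_class) &
    in_set(rec$target, rec$target_class)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L)
    warning("combined network is empty: no database edge connects two deregulated nodes")
  tf_ids <- unique(db$records$regulator[db$records$regulator_class == "TF"])
  reg_network(rec, tf_ids = tf_ids)
}

#' Infer deregulated miRNAs from deregulated genes
#'
#' Scenario-2 input: given only a deregulated gene set, return the miRNAs
#' whose target genes AND whose regulator TFs are both significantly
#' enriched within the deregulated genes.  Two hypergeometric tests are run
#' per candidate miRNA, each BH-adjusted across all candidates, and a miRNA
#' is returned when both adjusted P-values fall below `alpha`.
#'
#' The target-side universe is the union of all genes targeted by any miRNA
#' or regulated by any TF in the database; the TF-side universe is the set
#' of all TF-role regulators.
#'
#' @param db an [interaction_db()].
#' @param dereg_genes deregulated gene/TF IDs.
#' @param alpha BH-adjusted significance cutoff (default 0.001).
#' @return list with `mirnas` (character vector) and `detail` (one row per
#'   candidate miRNA with both tests' counts and P-values).
#' @export
infer_mirnas <- function(db, dereg_genes, alpha = 0.001) {
  stopifnot(inherits(db, "interaction_db"))
  rec <- db$records
  m2g <- rec[rec$interaction_type == "miRNA2gene", , drop = FALSE]
  t2m <- rec[rec$interaction_type == "TF2miRNA", , drop = FALSE]
  if (nrow(m2g) == 0L)
    stop("database has no miRNA2gene records; cannot infer miRNAs")

  gene_universe <- unique(c(m2g$target,
                            rec$target[rec$interaction_type == "TF2gene"]))
  tf_universe <- unique(rec$regulator[rec$regulator_class == "TF"])
  M_g <- length(gene_universe)
  M_t <- length(tf_universe)
  N_g <- length(intersect(dereg_genes, gene_universe))
  N_t <- length(intersect(dereg_genes, tf_universe))

  targets_of <- split(m2g$target, m2g$regulator)
  tfs_of <- split(t2m$regulator, t2m$target)
  candidates <- sort(names(targets_of))
  if (!length(candidates)) stop("no candidate miRNAs in database")

  detail <- do.call(rbind, lapply(candidates, function(mir) {
    tg <- unique(targets_of[[mir]])
    x_g <- length(intersect(tg, dereg_genes))
    tf <- unique(tfs_of[[mir]])
    x_t <- length(intersect(tf, dereg_genes))
    data.frame(mirna = mir,
               k_target = length(tg), x_target = x_g,
               k_tf = length(tf), x_tf = x_t,
               stringsAsFactors = FALSE)
  }))
  detail$p_target <- mapply(hypergeom_pvalue, x = detail$x_target,
                            k = detail$k_target,
                            MoreArgs = list(N = N_g, M = M_g))
  detail$p_tf <- mapply(hypergeom_pvalue, x = detail$x_tf, k = detail$k_tf,
                        MoreArgs = list(N = N_t, M = M_t))
  detail$p_target_adj <- bh_adjust(detail$p_target)
  detail$p_tf_adj <- bh_adjust(detail$p_tf)
  detail$significant <- detail$p_target_adj < alpha & detail$p_tf_adj < alpha

  if (!any(detail$x_target > 0L))
    warning("no candidate miRNA shares a target with the deregulated genes")
  list(mirnas = detail$mirna[detail$significant], detail = detail)
}

#' Extract the disease-specific subnetwork
#'
#' Keeps every interaction whose regulator node or target node is associated
#' with the disease; the node set is the endpoints of the retained edges
#' (no isolated associated nodes).
#'
#' @param net a [reg_network()] (non-empty).
#' @param assoc a [disease_associations()] object.
#' @return a [reg_network()] that is a subgraph of `net`.
#' @export
extract_disease_network <- function(net, assoc) {
  stopifnot(inherits(assoc, "disease_assoc"), igraph::ecount(net) > 0L)
  ids <- c(assoc$genes, assoc$mirnas)
  ed <- network_edges(net)
  keep <- ed$from %in% ids | ed$to %in% ids
  if (!any(keep))
    warning("no network edge touches a disease-associated node")
  sub <- igraph::subgraph_from_edges(net, igraph::E(net)[keep],
                                     delete.vertices = TRUE)
  as_reg_network(sub)
}

#' Coverage ratio between disease-specific and combined networks
#'
#' Node coverage is `N_d / N_t` (disease-network nodes over combined-network
#' nodes); edge coverage is the analogous edge-count ratio.
#'
#' @param disease_net disease-specific network, a subgraph of `combined_net`.
#' @param combined_net the combined network (non-empty).
#' @return object of class `coverage_report` with fields `N_d`, `N_t`,
#'   `node_CR`, `E_d`, `E_t`, `edge_CR`.
#' @export
coverage_ratio <- function(disease_net, combined_net) {
  stopifnot(igraph::vcount(combined_net) > 0L)
  dn <- network_nodes(disease_net)$name
  cn <- network_nodes(combined_net)$name
  de <- network_edges(disease_net)
  ce <- network_edges(combined_net)
  ekey <- function(e) paste(e$from, e$to, e$interaction_type, sep = "\r")
  if (!all(dn %in% cn) || !all(ekey(de) %in% ekey(ce)))
    stop("disease network is not a subgraph of the combined network")
  rep <- list(N_d = length(dn), N_t = length(cn),
              node_CR = length(dn) / length(cn),
              E_d = nrow(de), E_t = nrow(ce),
              edge_CR = if (nrow(ce) > 0) nrow(de) / nrow(ce) else NA_real_)
  structure(rep, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage ratio: nodes %d/%d = %.1f%%; edges %d/%d = %.1f%%\n",
              x$N_d, x$N_t, 100 * x$node_CR,
              x$E_d, x$E_t, 100 * x$edge_CR))
  invisible(x)
}

#' Degree distribution of a network
#'
#' @param net a [reg_network()].
#' @param mode `"total"`, `"in"` or `"out"` degree.
#' @return data frame (degree, count) sorted by degree; counts sum to the
#'   node count.
#' @export
degree_distribution_table <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  if (igraph::vcount(net) == 0L)
    return(data.frame(degree = integer(0), count = integer(0)))
  deg <- igraph::degree(net, mode = c(total = "all", `in` = "in", out = "out")[[mode]])
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Overlap between deregulated targets and database targets of deregulated
#' regulators
#'
#' For one interaction type, compares the input deregulated target set with
#' the set of database targets of the input deregulated regulators.
#' Overlap significance is assessed two ways: a hypergeometric test over the
#' type's target universe, and a randomization test that redraws regulator
#' sets of the same size from the database's regulator universe (this
#' controls for the regulators' target-set sizes); the empirical P-value is
#' the add-one-smoothed fraction of draws whose overlap reaches the observed
#' one.
#'
#' @param db an [interaction_db()].
#' @param interaction_type one of the four type tokens.
#' @param dereg_regulators deregulated regulator IDs.
#' @param dereg_targets deregulated target IDs.
#' @param universe_size hypergeometric universe size (default: number of
#'   distinct targets of this type in the database).
#' @param n_random number of randomization draws (default 1000).
#' @param seed optional RNG seed, recorded in the report.
#' @return object of class `overlap_report`.
#' @export
overlap_report <- function(db, interaction_type, dereg_regulators,
                           dereg_targets, universe_size = NULL,
                           n_random = 1000, seed = NULL) {
  stopifnot(inherits(db, "interaction_db"),
            interaction_type %in% INTERACTION_TYPES)
  uni <- db$universes[[interaction_type]]
  if (!length(uni$regulators))
    stop("database has no regulators of type ", interaction_type)
  rec <- db$records[db$records$interaction_type == interaction_type, ,
                    drop = FALSE]
  targets_of <- split(rec$target, rec$regulator)

  obs_regs <- intersect(dereg_regulators, uni$regulators)
  db_targets <- unique(unlist(targets_of[obs_regs], use.names = FALSE))
  if (is.null(db_targets)) db_targets <- character(0)
  M <- if (is.null(universe_size)) length(uni$targets) else universe_size
  dereg_in_uni <- intersect(dereg_targets, uni$targets)
  x <- length(intersect(db_targets, dereg_targets))
  k <- length(db_targets)
  N <- length(dereg_in_uni)
  hyper_p <- hypergeom_pvalue(min(x, min(k, N)), k, N, M)

  if (!is.null(seed)) set.seed(seed)
  n_regs <- length(obs_regs)
  hits <- 0L
  for (i in seq_len(n_random)) {
    rr <- sample(uni$regulators, n_regs)
    rt <- unique(unlist(targets_of[rr], use.names = FALSE))
    if (length(intersect(rt, dereg_targets)) >= x) hits <- hits + 1L
  }
  structure(list(interaction_type = interaction_type,
                 n_dereg_targets = length(dereg_targets),
                 n_db_targets_of_dereg_regulators = k,
                 n_overlap = x, universe_size = M,
                 hypergeom_p = hyper_p,
                 randomization_p = (hits + 1) / (n_random + 1),
                 n_random = n_random, seed = seed),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0("Overlap report [%s]: %d deregulated targets, %d DB targets",
                     " of deregulated regulators, overlap %d\n",
                     "  hypergeometric P = %.3g; randomization P = %.3g (n = %d)\n"),
              x$interaction_type, x$n_dereg_targets,
              x$n_db_targets_of_dereg_regulators, x$n_overlap,
              x$hypergeom_p, x$randomization_p, x$n_random))
  invisible(x)
}
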