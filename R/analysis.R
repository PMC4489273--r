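#' Full co-regulatory network analysis
#'
#' Single entry point wiring the whole pipeline: builds the combined
#' TF-miRNA co-regulatory network from an interaction database and
#' deregulated gene/miRNA sets (inferring the miRNA set from the genes when
#' none is given), optionally extracts the disease-specific subnetwork and
#' its coverage ratios, identifies key nodes (four centralities and the
#' minimum dominating set), detects TF-miRNA-gene feed-forward-loop motifs
#' and their significance against degree-preserving random networks, and
#' runs over-representation analysis of the network genes when annotations
#' are supplied.
#'
#' @param db an [interaction_db()].
#' @param genes deregulated gene/TF IDs.
#' @param mirnas deregulated miRNA IDs, or `NULL` to infer them from
#'   `genes` ([infer_mirnas()]).
#' @param assoc optional [disease_associations()] enabling the
#'   disease-specific analysis level.
#' @param annotations optional [annotation_table()] enabling ORA.
#' @param alpha significance cutoff for pair tests and ORA (default 0.05).
#' @param infer_alpha BH cutoff for miRNA inference (default 0.001).
#' @param fraction top-centrality fraction for key nodes (default 0.10).
#' @param per_class stratify key-node selection by node class.
#' @param domination MDS convention, see [minimum_dominating_set()].
#' @param n_random_motifs randomized networks for motif significance
#'   (default 100); set to 0 to skip the randomization stage.
#' @param seed RNG seed controlling every stochastic stage.
#' @return object of class `coreg_analysis`.
#' @export
coreg_analysis <- function(db, genes, mirnas = NULL, assoc = NULL,
                           annotations = NULL, alpha = 0.05,
                           infer_alpha = 0.001, fraction = 0.10,
                           per_class = FALSE, domination = "closed",
                           n_random_motifs = 100, seed = NULL) {
  stopifnot(inherits(db, "interaction_db"))
  inferred <- NULL
  if (is.null(mirnas)) {
    inferred <- infer_mirnas(db, genes, alpha = infer_alpha)
    mirnas <- inferred$mirnas
  }
  combined <- build_combined_network(db, genes, mirnas)

  disease_net <- NULL
  coverage <- NULL
  if (!is.null(assoc) && igraph::ecount(combined) > 0L) {
    disease_net <- extract_disease_network(combined, assoc)
    coverage <- coverage_ratio(disease_net, combined)
  }

  net <- if (!is.null(disease_net) && igraph::ecount(disease_net) > 0L)
    disease_net else combined

  pairs <- motifs <- signif <- keynodes <- ora_genes <- NULL
  if (igraph::ecount(combined) > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pairs <- suppressWarnings(significant_pairs(combined, alpha = alpha))
    motifs <- find_ffl_motifs(combined, pairs)
    if (n_random_motifs > 0L)
      signif <- motif_significance(combined, alpha = alpha,
                                   n_networks = n_random_motifs)
    keynodes <- key_node_report(net, fraction = fraction,
                                per_class = per_class,
                                domination = domination)
    if (!is.null(annotations)) {
      nd <- network_nodes(combined)
      gene_nodes <- nd$name[nd$node_class %in% c("gene", "TF")]
      universe <- unique(c(names(entity_terms(annotations)), gene_nodes))
      ora_genes <- ora(gene_nodes, annotations, universe, alpha = alpha)
    }
  }

  structure(list(db = db, genes = genes, mirnas = mirnas,
                 inferred_mirnas = inferred, combined = combined,
                 disease_net = disease_net, coverage = coverage,
                 pairs = pairs, motifs = motifs,
                 motif_significance = signif, keynodes = keynodes,
                 ora_genes = ora_genes,
                 params = list(alpha = alpha, infer_alpha = infer_alpha,
                               fraction = fraction, domination = domination,
                               n_random_motifs = n_random_motifs,
                               seed = seed)),
            class = "coreg_analysis")
}

#' @export
print.coreg_analysis <- function(x, ...) {
  cat("TF-miRNA co-regulatory network analysis\n")
  cat(sprintf("  input: %d deregulated genes/TFs, %d deregulated miRNAs%s\n",
              length(x$genes), length(x$mirnas),
              if (!is.null(x$inferred_mirnas)) " (inferred)" else ""))
  cat("  combined network: ")
  cat(sprintf("%d nodes, %d edges\n", igraph::vcount(x$combined),
              igraph::ecount(x$combined)))
  if (!is.null(x$coverage))
    cat(sprintf("  disease network: %d nodes, %d edges (node CR %.1f%%, edge CR %.1f%%)\n",
                x$coverage$N_d, x$coverage$E_d,
                100 * x$coverage$node_CR, 100 * x$coverage$edge_CR))
  if (!is.null(x$motifs))
    cat("  motifs:", nrow(x$motifs), "instances (",
        paste(sprintf("%s=%d", MOTIF_TYPES, count_motifs(x$motifs)),
              collapse = ", "), ")\n")
  if (!is.null(x$keynodes))
    cat(sprintf("  key nodes: union %d, common %d, dominating set %d\n",
                length(x$keynodes$union_set), length(x$keynodes$common_set),
                length(x$keynodes$mds_set)))
  invisible(x)
}

#' @export
summary.coreg_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$motif_significance)) {
    cat("\n")
    print(object$motif_significance)
  }
  if (!is.null(object$keynodes)) {
    cat("\nKey players (union of four centrality top sets):\n  ")
    cat(paste(object$keynodes$union_set, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot the degree distribution of the analysed network
#'
#' @param x a `coreg_analysis` object.
#' @param which `"combined"` or `"disease"` network.
#' @param mode degree mode, see [degree_distribution_table()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.coreg_analysis <- function(x, which = c("combined", "disease"),
                                mode = "total", ...) {
  which <- match.arg(which)
  net <- if (which == "disease" && !is.null(x$disease_net)) x$disease_net
         else x$combined
  dd <- degree_distribution_table(net, mode = mode)
  graphics::plot(dd$degree, dd$count, log = "xy", pch = 19,
                 xlab = "degree", ylab = "node count",
                 main = paste(which, "network degree distribution"), ...)
  invisible(dd)
}

#' Write the full report bundle of an analysis
#'
#' Emits networks (edge TSV and GraphML), the pair, motif, significance,
#' key-node, coverage, inferred-miRNA and ORA tables, degree histograms,
#' and a run manifest recording the seed and package version.
#'
#' @param x a [coreg_analysis()] object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_reports <- function(x, out_dir) {
  stopifnot(inherits(x, "coreg_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  tsv <- function(df, name) write.table(df, p(name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  suppressWarnings({
    write_network(x$combined, p("combined_network.tsv"), "edge_tsv")
    write_network(x$combined, p("combined_network.graphml"), "graphml")
    if (!is.null(x$disease_net)) {
      write_network(x$disease_net, p("disease_network.tsv"), "edge_tsv")
      write_network(x$disease_net, p("disease_network.graphml"), "graphml")
    }
  })
  tsv(degree_distribution_table(x$combined), "degree_distribution.tsv")
  if (!is.null(x$coverage))
    tsv(data.frame(N_d = x$coverage$N_d, N_t = x$coverage$N_t,
                   node_CR_pct = round(100 * x$coverage$node_CR, 1),
                   E_d = x$coverage$E_d, E_t = x$coverage$E_t,
                   edge_CR_pct = round(100 * x$coverage$edge_CR, 1)),
        "coverage_report.tsv")
  if (!is.null(x$inferred_mirnas))
    tsv(x$inferred_mirnas$detail, "inferred_mirnas.tsv")
  if (!is.null(x$pairs)) tsv(x$pairs, "significant_pairs.tsv")
  if (!is.null(x$motifs)) tsv(x$motifs, "motif_instances.tsv")
  if (!is.null(x$motif_significance))
    tsv(x$motif_significance, "motif_significance.tsv")
  if (!is.null(x$keynodes))
    tsv(as.data.frame(x$keynodes), "key_nodes.tsv")
  if (!is.null(x$ora_genes)) tsv(x$ora_genes, "ora_genes.tsv")
  manifest <- c(
    paste0("package: mirtfnet ",
           as.character(utils::packageVersion("mirtfnet"))),
    paste0("R: ", R.version.string),
    paste0("seed: ", if (is.null(x$params$seed)) "NULL" else x$params$seed),
    paste0("alpha: ", x$params$alpha),
    paste0("n_random_motifs: ", x$params$n_random_motifs),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  writeLines(manifest, p("manifest.txt"))
  invisible(p("manifest.txt"))
}

#' Run the full analysis from file paths
#'
#' Thin file-based wrapper over [coreg_analysis()] plus [write_reports()],
#' the programmatic equivalent of the command-line `run-all` subcommand.
#'
#' @param interactions path to the interaction TSV.
#' @param genes path to the deregulated gene list.
#' @param mirnas optional path to the deregulated miRNA list (omit to infer
#'   the miRNAs from the genes).
#' @param disease_assoc optional path to a disease-association TSV.
#' @param annotations optional path to a GMT annotation file.
#' @param out_dir report output directory.
#' @param evidence evidence filter for the database.
#' @param ... further arguments for [coreg_analysis()].
#' @return the [coreg_analysis()] object, invisibly.
#' @export
run_full_analysis <- function(interactions, genes, mirnas = NULL,
                              disease_assoc = NULL, annotations = NULL,
                              out_dir = "mirtfnet_out",
                              evidence = "both", ...) {
  db <- read_interaction_table(interactions, evidence_filter = evidence,
                               quiet = TRUE)
  gene_set <- read_id_list(genes)
  mirna_set <- if (is.null(mirnas)) NULL else read_id_list(mirnas)
  assoc <- if (is.null(disease_assoc)) NULL
           else read_disease_associations(disease_assoc)
  annot <- if (is.null(annotations)) NULL else read_gmt(annotations)
  res <- coreg_analysis(db, gene_set, mirna_set, assoc = assoc,
                        annotations = annot, ...)
  write_reports(res, out_dir)
  invisible(res)
}
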