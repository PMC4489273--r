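#' Node centrality scores
#'
#' Degree centrality is total (in + out) degree on the directed network;
#' closeness, betweenness and eigenvector centrality are computed on the
#' undirected skeleton, since regulatory networks mix edge directions
#' across regulator classes.  Closeness of isolated vertices is reported
#' as 0.
#'
#' @param net a [reg_network()] (non-empty).
#' @param measure one of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"eigenvector"`.
#' @return named numeric vector (node -> score), all finite.
#' @export
centrality_scores <- function(net,
                              measure = c("degree", "closeness",
                                          "betweenness", "eigenvector")) {
  measure <- match.arg(measure)
  stopifnot(igraph::vcount(net) > 0L)
  if (measure == "degree")
    return(igraph::degree(net, mode = "all"))
  ug <- igraph::as_undirected(net, mode = "collapse")
  sc <- switch(measure,
    closeness = suppressWarnings(igraph::closeness(ug)),
    betweenness = igraph::betweenness(ug),
    eigenvector = {
      ev <- tryCatch(igraph::eigen_centrality(ug, directed = FALSE)$vector,
                     error = function(e)
                       stop("eigenvector centrality failed to converge; ",
                            "consider capping iterations or using another measure"))
      ev
    })
  sc[!is.finite(sc)] <- 0
  sc
}

#' Top-scoring nodes by centrality
#'
#' Returns the top `fraction` of nodes (default 10%), size
#' `ceiling(fraction * n)` with all cutoff ties included.  With `classes`
#' given, the selection is stratified per node class and the strata are
#' unioned.
#'
#' @param scores named numeric vector from [centrality_scores()].
#' @param fraction fraction in (0, 1\].
#' @param classes optional named character vector (node -> class) enabling
#'   per-class stratification.
#' @return character vector of node IDs.
#' @export
top_key_nodes <- function(scores, fraction = 0.10, classes = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  pick <- function(sc) {
    if (!length(sc)) return(character(0))
    size <- ceiling(fraction * length(sc))
    thr <- sort(sc, decreasing = TRUE)[size]
    names(sc)[sc >= thr]
  }
  if (is.null(classes)) return(pick(scores))
  strata <- split(scores, classes[names(scores)])
  unique(unlist(lapply(strata, pick), use.names = FALSE))
}

#' Union and intersection of per-measure key-node sets
#'
#' @param per_measure_sets list of character vectors (at least one).
#' @return list with elements `union` and `common`.
#' @export
union_and_common <- function(per_measure_sets) {
  stopifnot(length(per_measure_sets) >= 1L)
  list(union = sort(unique(unlist(per_measure_sets, use.names = FALSE))),
       common = sort(Reduce(intersect, per_measure_sets)))
}

#' Minimum dominating set of a network
#'
#' Finds a smallest node set such that every node is dominated, on the
#' undirected skeleton, solved per connected component.  Under closed
#' domination (default, the standard MDS) a node dominates itself and its
#' neighbors; under open domination it dominates its neighbors only, the
#' reading implied by a domination constraint with a zero-diagonal
#' adjacency matrix.  The exact solver is a branch-and-bound that returns a
#' provably minimum set; the greedy solver repeatedly takes the node
#' covering most uncovered nodes (ties broken by node ID).
#'
#' @param net a [reg_network()] or any igraph.
#' @param domination `"closed"` or `"open"`.
#' @param solver `"auto"` (exact for components up to
#'   `exact_limit` nodes, greedy above), `"exact"` or `"greedy"`.
#' @param exact_limit component-size cap for the exact solver under
#'   `"auto"` (default 150).
#' @return character vector of dominating node IDs.
#' @export
minimum_dominating_set <- function(net, domination = c("closed", "open"),
                                   solver = c("auto", "exact", "greedy"),
                                   exact_limit = 150L) {
  domination <- match.arg(domination)
  solver <- match.arg(solver)
  n <- igraph::vcount(net)
  if (n == 0L) return(character(0))
  ug <- igraph::as_undirected(net, mode = "collapse")
  ug <- igraph::simplify(ug)
  ids <- igraph::V(ug)$name
  adj <- lapply(igraph::adjacent_vertices(ug, igraph::V(ug)), as.integer)

  if (domination == "open") {
    iso <- which(lengths(adj) == 0L)
    if (length(iso))
      stop("open domination infeasible: isolated node '", ids[iso[1]], "'")
  }
  # cover[[v]]: nodes dominated when v is chosen
  cover <- lapply(seq_len(n), function(v)
    if (domination == "closed") c(v, adj[[v]]) else adj[[v]])

  comp <- igraph::components(ug)$membership
  chosen <- integer(0)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    use_exact <- solver == "exact" ||
      (solver == "auto" && length(members) <= exact_limit)
    sol <- if (use_exact) mds_exact(members, cover)
           else mds_greedy(members, cover, ids)
    chosen <- c(chosen, sol)
  }
  sort(ids[chosen])
}

# Greedy set cover: most newly-covered first, ties by node ID.
mds_greedy <- function(members, cover, ids) {
  uncovered <- rep(FALSE, length(cover))
  uncovered[members] <- TRUE
  ord <- members[order(ids[members])]
  chosen <- integer(0)
  while (any(uncovered)) {
    gain <- vapply(ord, function(v) sum(uncovered[cover[[v]]]), 0L)
    best <- ord[which.max(gain)]
    if (gain[which.max(gain)] == 0L)
      stop("greedy domination stalled; graph violates feasibility")
    chosen <- c(chosen, best)
    uncovered[cover[[best]]] <- FALSE
  }
  chosen
}

# Exact branch-and-bound: branch on the dominators of the hardest-to-cover
# node; prune with a simple covering lower bound.
mds_exact <- function(members, cover) {
  n_all <- length(cover)
  in_comp <- rep(FALSE, n_all)
  in_comp[members] <- TRUE
  # dominators[[u]]: nodes whose choice covers u
  dominators <- vector("list", n_all)
  for (v in members)
    for (u in cover[[v]])
      if (in_comp[u]) dominators[[u]] <- c(dominators[[u]], v)

  ids_dummy <- as.character(seq_len(n_all))
  best <- mds_greedy(members, cover, ids_dummy)
  best_size <- length(best)
  max_cover <- max(vapply(members, function(v) length(cover[[v]]), 0L), 1L)

  rec <- function(uncovered, chosen) {
    n_unc <- sum(uncovered)
    if (n_unc == 0L) {
      if (length(chosen) < best_size) {
        best <<- chosen
        best_size <<- length(chosen)
      }
      return(invisible(NULL))
    }
    lb <- length(chosen) + ceiling(n_unc / max_cover)
    if (lb >= best_size) return(invisible(NULL))
    unc <- which(uncovered)
    # branch on the uncovered node with fewest dominators
    u <- unc[which.min(vapply(unc, function(z) length(dominators[[z]]), 0L))]
    cands <- dominators[[u]]
    gains <- vapply(cands, function(v) sum(uncovered[cover[[v]]]), 0L)
    for (v in cands[order(-gains)]) {
      new_unc <- uncovered
      new_unc[cover[[v]]] <- FALSE
      rec(new_unc, c(chosen, v))
    }
    invisible(NULL)
  }
  unc0 <- rep(FALSE, n_all)
  unc0[members] <- TRUE
  rec(unc0, integer(0))
  best
}

#' Key-node report
#'
#' Computes the four centrality measures, their top-`fraction` node sets,
#' the union and intersection of those sets, and the minimum dominating
#' set.
#'
#' @param net a [reg_network()] (non-empty).
#' @param fraction top fraction per measure (default 0.10).
#' @param per_class stratify the top sets by node class.
#' @param domination,solver passed to [minimum_dominating_set()].
#' @return object of class `key_node_report`.
#' @export
key_node_report <- function(net, fraction = 0.10, per_class = FALSE,
                            domination = "closed", solver = "auto") {
  measures <- c("degree", "closeness", "betweenness", "eigenvector")
  classes <- if (per_class)
    setNames(igraph::V(net)$node_class, igraph::V(net)$name) else NULL
  scores <- lapply(setNames(measures, measures),
                   function(m) centrality_scores(net, m))
  top <- lapply(scores, top_key_nodes, fraction = fraction, classes = classes)
  uc <- union_and_common(top)
  structure(list(scores = scores, top_sets = top,
                 union_set = uc$union, common_set = uc$common,
                 mds_set = minimum_dominating_set(net, domination, solver),
                 fraction = fraction, per_class = per_class,
                 domination = domination),
            class = "key_node_report")
}

#' @export
print.key_node_report <- function(x, ...) {
  cat(sprintf("Key-node report (top %.0f%%%s, %s domination)\n",
              100 * x$fraction, if (x$per_class) ", per class" else "",
              x$domination))
  for (m in names(x$top_sets))
    cat(sprintf("  %-12s %d nodes\n", m, length(x$top_sets[[m]])))
  cat(sprintf("  union %d, common %d, dominating set %d\n",
              length(x$union_set), length(x$common_set), length(x$mds_set)))
  invisible(x)
}

#' Tabular form of a key-node report
#'
#' @param x a [key_node_report()].
#' @param ... unused.
#' @return data frame with one row per node: scores plus membership flags.
#' @export
as.data.frame.key_node_report <- function(x, ...) {
  nodes <- names(x$scores$degree)
  df <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (m in names(x$scores)) {
    df[[m]] <- unname(x$scores[[m]][nodes])
    df[[paste0("top_", m)]] <- nodes %in% x$top_sets[[m]]
  }
  df$in_union <- nodes %in% x$union_set
  df$in_common <- nodes %in% x$common_set
  df$in_mds <- nodes %in% x$mds_set
  df
}
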