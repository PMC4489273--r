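#' Configuration for the synthetic-data generator
#'
#' The generator emulates the inputs of a co-regulatory network study: a
#' typed interaction database with background edges drawn independently per
#' interaction type, plus planted structure with known ground truth —
#' TF-miRNA pairs of each motif class sharing a block of target genes,
#' miRNAs whose targets and regulator TFs concentrate inside a designated
#' deregulated gene pool, and annotation modules shared by co-targeted
#' genes.
#'
#' @param n_tfs,n_genes,n_mirnas node-pool sizes.
#' @param density per-type background edge probability over the allowed
#'   (class-consistent) node pairs; named vector over the four interaction
#'   types.
#' @param planted_motifs named integer vector: planted TF-miRNA pairs per
#'   motif class.
#' @param shared_targets_per_pair common target genes given to each planted
#'   pair (also the planted functional-module size).
#' @param n_enriched_mirnas miRNAs planted as inferable from the
#'   deregulated gene pool.
#' @param targets_per_enriched_mirna planted targets (inside the pool) per
#'   enriched miRNA.
#' @param tfs_per_enriched_mirna deregulated TFs regulating each enriched
#'   miRNA.
#' @param dereg_pool_size designated deregulated background gene-pool size.
#' @param dereg_background_fraction fraction of the remaining genes added
#'   to the deregulated gene set as noise.
#' @param mirna_background_fraction ditto for miRNAs.
#' @param validated_fraction fraction of background records tagged
#'   `validated` (planted records are always validated).
#' @param disease_fraction fraction of deregulated nodes carrying a disease
#'   association.
#' @param n_terms,terms_per_gene annotation vocabulary size and terms drawn
#'   per gene.
#' @param module_terms_shared dedicated terms shared by all genes of a
#'   planted module (replacing that many background terms).
#' @param seed RNG seed; all generators derive their streams from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_tfs = 100, n_genes = 400, n_mirnas = 30,
                         density = c(TF2gene = 0.02, TF2miRNA = 0.01,
                                     miRNA2gene = 0.02, miRNA2miRNA = 0.01),
                         planted_motifs = c(coreg_FFL = 2, TF_FFL = 2,
                                            miRNA_FFL = 2, composite_FFL = 2),
                         shared_targets_per_pair = 10,
                         n_enriched_mirnas = 2,
                         targets_per_enriched_mirna = 30,
                         tfs_per_enriched_mirna = 10,
                         dereg_pool_size = 40,
                         dereg_background_fraction = 0.15,
                         mirna_background_fraction = 0.3,
                         validated_fraction = 0.7,
                         disease_fraction = 0.5,
                         n_terms = 200, terms_per_gene = 5,
                         module_terms_shared = 3,
                         seed = 1) {
  density <- density[INTERACTION_TYPES]
  if (any(is.na(density) | density < 0 | density > 1))
    stop("density must give a probability in [0, 1] for each interaction type")
  planted_motifs <- planted_motifs[MOTIF_TYPES]
  planted_motifs[is.na(planted_motifs)] <- 0L
  names(planted_motifs) <- MOTIF_TYPES
  n_pairs <- sum(planted_motifs)
  if (n_pairs + n_enriched_mirnas > n_mirnas)
    stop("not enough miRNAs for the requested planted structure")
  need_supp <- if (n_enriched_mirnas > 0) tfs_per_enriched_mirna else 0
  if (n_pairs + need_supp > n_tfs)
    stop("not enough TFs for the requested planted structure")
  if (n_pairs * shared_targets_per_pair + dereg_pool_size > n_genes)
    stop("not enough genes for the requested planted structure")
  if (module_terms_shared > terms_per_gene)
    stop("module_terms_shared cannot exceed terms_per_gene")
  structure(as.list(environment()), class = "synth_config")
}

# sample background (regulator, target) pairs with probability p each
sample_pairs <- function(regulators, targets, p, no_self = FALSE) {
  nr <- length(regulators); nt <- length(targets)
  npairs <- nr * nt
  if (npairs == 0L || p <= 0) return(NULL)
  k <- stats::rbinom(1L, npairs, p)
  if (k == 0L) return(NULL)
  idx <- sample.int(npairs, k) - 1L
  df <- data.frame(regulator = regulators[idx %% nr + 1L],
                   target = targets[idx %/% nr + 1L],
                   stringsAsFactors = FALSE)
  if (no_self) df <- df[df$regulator != df$target, , drop = FALSE]
  df
}

#' Generate a synthetic interaction database with planted structure
#'
#' @param config a [synth_config()].
#' @return list with elements `db` (an [interaction_db()]) and `truth`
#'   (ground-truth record of every planted object: the planted pairs and
#'   their shared-target modules, the enriched miRNAs, their supporting
#'   TFs, and the deterministic part of the deregulated sets).
#' @export
generate_db <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tfs <- paste0("TF", seq_len(config$n_tfs))
  genes <- paste0("G", seq_len(config$n_genes))
  mirnas <- paste0("hsa-mir-", seq_len(config$n_mirnas))

  n_pairs <- sum(config$planted_motifs)
  pair_types <- rep(MOTIF_TYPES, config$planted_motifs)
  pair_tfs <- tfs[seq_len(n_pairs)]
  pair_mirs <- mirnas[seq_len(n_pairs)]
  shared <- split(genes[seq_len(n_pairs * config$shared_targets_per_pair)],
                  rep(seq_len(n_pairs), each = config$shared_targets_per_pair))
  used_genes <- n_pairs * config$shared_targets_per_pair
  pool <- genes[used_genes + seq_len(config$dereg_pool_size)]
  enriched <- mirnas[n_pairs + seq_len(config$n_enriched_mirnas)]
  supp_tfs <- if (config$n_enriched_mirnas > 0)
    tfs[n_pairs + seq_len(config$tfs_per_enriched_mirna)] else character(0)

  # background edges, independently per interaction type
  bg <- list(
    TF2gene     = sample_pairs(tfs, genes, config$density[["TF2gene"]]),
    TF2miRNA    = sample_pairs(tfs, mirnas, config$density[["TF2miRNA"]]),
    miRNA2gene  = sample_pairs(mirnas, c(genes, tfs),
                               config$density[["miRNA2gene"]]),
    miRNA2miRNA = sample_pairs(mirnas, mirnas,
                               config$density[["miRNA2miRNA"]], no_self = TRUE))
  rec <- do.call(rbind, lapply(names(bg), function(tp) {
    if (is.null(bg[[tp]]) || nrow(bg[[tp]]) == 0L) return(NULL)
    cbind(bg[[tp]], interaction_type = tp, stringsAsFactors = FALSE)
  }))
  if (is.null(rec) || nrow(rec) == 0L)
    rec <- data.frame(regulator = character(0), target = character(0),
                      interaction_type = character(0),
                      evidence = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  else {
    rec$evidence <- ifelse(stats::runif(nrow(rec)) < config$validated_fraction,
                           "validated", "predicted")
    rec$source <- "background"
  }

  add <- function(rec, regulator, target, type) {
    rbind(rec, data.frame(regulator = regulator, target = target,
                          interaction_type = type, evidence = "validated",
                          source = "planted", stringsAsFactors = FALSE))
  }
  drop_edge <- function(rec, regulator, target, type) {
    rec[!(rec$regulator == regulator & rec$target == target &
            rec$interaction_type == type), , drop = FALSE]
  }

  # planted motif pairs: shared targets plus class-defining TF<->miRNA edges
  for (i in seq_len(n_pairs)) {
    tf <- pair_tfs[i]; mir <- pair_mirs[i]; tg <- shared[[i]]
    rec <- add(rec, rep(tf, length(tg)), tg, "TF2gene")
    rec <- add(rec, rep(mir, length(tg)), tg, "miRNA2gene")
    type <- pair_types[i]
    if (type %in% c("TF_FFL", "composite_FFL"))
      rec <- add(rec, tf, mir, "TF2miRNA")
    else
      rec <- drop_edge(rec, tf, mir, "TF2miRNA")
    if (type %in% c("miRNA_FFL", "composite_FFL"))
      rec <- add(rec, mir, tf, "miRNA2gene")
    else
      rec <- drop_edge(rec, mir, tf, "miRNA2gene")
  }

  # planted enriched miRNAs: targets inside the pool, regulators from the
  # deregulated supporting TFs
  for (mir in enriched) {
    tg <- sample(pool, config$targets_per_enriched_mirna)
    rec <- add(rec, rep(mir, length(tg)), tg, "miRNA2gene")
    rec <- add(rec, supp_tfs, rep(mir, length(supp_tfs)), "TF2miRNA")
  }

  truth <- list(
    pairs = data.frame(motif_type = pair_types, tf = pair_tfs,
                       mirna = pair_mirs, stringsAsFactors = FALSE),
    shared_targets = setNames(shared, paste(pair_tfs, pair_mirs, sep = "|")),
    modules = setNames(shared, paste0("module", seq_len(n_pairs))),
    enriched_mirnas = enriched,
    supporting_tfs = supp_tfs,
    dereg_pool_genes = pool,
    dereg_genes_core = unique(c(pool, unlist(shared, use.names = FALSE),
                                pair_tfs, supp_tfs)),
    dereg_mirnas_core = unique(c(pair_mirs, enriched)),
    node_pools = list(tfs = tfs, genes = genes, mirnas = mirnas),
    seed = config$seed)
  list(db = interaction_db(rec), truth = truth)
}

#' Generate deregulated gene and miRNA sets covering the planted structure
#'
#' The deterministic core (planted pairs' TFs and shared targets, the
#' deregulated gene pool, supporting TFs, planted and motif miRNAs) is
#' always included; background noise nodes are added at the configured
#' fractions.
#'
#' @param config a [synth_config()].
#' @param truth the `truth` element from [generate_db()].
#' @return list with `genes` and `mirnas` character vectors.
#' @export
generate_dereg_sets <- function(config, truth) {
  set.seed(config$seed + 1L)
  rest_genes <- setdiff(truth$node_pools$genes, truth$dereg_genes_core)
  n_bg <- round(config$dereg_background_fraction * length(rest_genes))
  genes <- c(truth$dereg_genes_core, sample(rest_genes, n_bg))
  rest_mirs <- setdiff(truth$node_pools$mirnas, truth$dereg_mirnas_core)
  n_bgm <- round(config$mirna_background_fraction * length(rest_mirs))
  mirnas <- c(truth$dereg_mirnas_core, sample(rest_mirs, n_bgm))
  list(genes = genes, mirnas = mirnas)
}

#' Generate an annotation table with planted functional modules
#'
#' Every gene and TF receives `terms_per_gene` background terms drawn
#' independently from the vocabulary; each planted module (the shared
#' targets of one planted pair) additionally shares `module_terms_shared`
#' dedicated terms, replacing that many background terms, which gives
#' co-targeted genes measurably higher pairwise similarity than background
#' pairs.
#'
#' @param config a [synth_config()].
#' @param truth the `truth` element from [generate_db()].
#' @return an [annotation_table()].
#' @export
generate_annotations <- function(config, truth) {
  set.seed(config$seed + 2L)
  vocab <- paste0("T", seq_len(config$n_terms))
  entities <- c(truth$node_pools$genes, truth$node_pools$tfs)
  g2t <- setNames(lapply(entities, function(g)
    sample(vocab, config$terms_per_gene)), entities)
  for (m in seq_along(truth$modules)) {
    mod_terms <- paste0("MOD", m, "_", seq_len(config$module_terms_shared))
    for (g in truth$modules[[m]])
      g2t[[g]] <- c(mod_terms,
                    g2t[[g]][seq_len(config$terms_per_gene -
                                       config$module_terms_shared)])
  }
  ent <- rep(names(g2t), lengths(g2t))
  trm <- unlist(g2t, use.names = FALSE)
  annotation_table(split(ent, trm))
}

#' Generate disease associations over the deregulated sets
#'
#' Samples the configured fraction of the deregulated genes and miRNAs as
#' disease-associated.
#'
#' @param config a [synth_config()].
#' @param dereg list with `genes` and `mirnas`, from
#'   [generate_dereg_sets()].
#' @param disease disease label.
#' @return a [disease_associations()] object.
#' @export
generate_disease_associations <- function(config, dereg,
                                          disease = "synthetic disease") {
  set.seed(config$seed + 3L)
  ng <- round(config$disease_fraction * length(dereg$genes))
  nm <- round(config$disease_fraction * length(dereg$mirnas))
  disease_associations(disease,
                       genes = sample(dereg$genes, ng),
                       mirnas = sample(dereg$mirnas, nm))
}

#' Generate a full synthetic study
#'
#' Convenience wrapper bundling database, deregulated sets, annotations and
#' disease associations.
#'
#' @param config a [synth_config()].
#' @return list with `db`, `truth`, `dereg`, `annotations`, `assoc`.
#' @export
generate_study <- function(config = synth_config()) {
  gd <- generate_db(config)
  dereg <- generate_dereg_sets(config, gd$truth)
  list(db = gd$db, truth = gd$truth, dereg = dereg,
       annotations = generate_annotations(config, gd$truth),
       assoc = generate_disease_associations(config, dereg))
}
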