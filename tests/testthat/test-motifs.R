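# deterministic network holding one planted triple of each motif class:
# pair i co-targets gene block i; class-defining TF<->miRNA edges differ
four_class_net <- function(shared = 3) {
  rec <- NULL
  add <- function(rec, r, t, tp)
    rbind(rec, data.frame(regulator = r, target = t, interaction_type = tp,
                          evidence = "validated", source = "t",
                          stringsAsFactors = FALSE))
  for (i in 1:4) {
    tf <- paste0("TF", i); mir <- paste0("hsa-mir-", i)
    genes <- paste0("G", (i - 1) * shared + seq_len(shared))
    rec <- add(rec, rep(tf, shared), genes, "TF2gene")
    rec <- add(rec, rep(mir, shared), genes, "miRNA2gene")
    if (i %in% c(2, 4)) rec <- add(rec, tf, mir, "TF2miRNA")
    if (i %in% c(3, 4)) rec <- add(rec, mir, tf, "miRNA2gene")
  }
  reg_network(rec)
}

test_that("pair test counts and P-values follow the shared-target model", {
  net <- four_class_net()
  res <- significant_pairs(net, all = TRUE)
  # only same-index pairs share targets; 4 tested pairs
  expect_equal(nrow(res), 4L)
  expect_true(all(res$x == 3))
  r1 <- res[res$tf == "TF1", ]
  # M = all co-targeted genes plus the miRNA-repressed TFs (miRNA_FFL and
  # composite add TF3, TF4 as miRNA2gene targets)
  expect_equal(r1$M, 14L)
  expect_equal(r1$k, 3L)  # hsa-mir-1 targets G1..G3 only
  expect_equal(r1$p_raw,
               oracle_hyper_tail(r1$x, r1$k, r1$N, r1$M))
  expect_equal(res$p_adjusted, bh_adjust(res$p_raw))
})

test_that("pairs sharing no target are not tested", {
  rec <- data.frame(regulator = c("TF1", "hsa-mir-1"), target = c("G1", "G2"),
                    interaction_type = c("TF2gene", "miRNA2gene"),
                    evidence = "validated", source = "t",
                    stringsAsFactors = FALSE)
  expect_warning(res <- significant_pairs(reg_network(rec), all = TRUE),
                 "no TF-miRNA pair")
  expect_equal(nrow(res), 0L)
})

test_that("planted heavy-overlap pairs are the significant ones", {
  set.seed(61)
  # 2 planted pairs sharing 6 targets each, 8 background pairs with 1 shared
  rec <- NULL
  add <- function(rec, r, t, tp)
    rbind(rec, data.frame(regulator = r, target = t, interaction_type = tp,
                          evidence = "validated", source = "t",
                          stringsAsFactors = FALSE))
  genes <- paste0("G", 1:60)
  for (i in 1:2) {
    blk <- genes[(i - 1) * 6 + 1:6]
    rec <- add(rec, rep(paste0("TF", i), 6), blk, "TF2gene")
    rec <- add(rec, rep(paste0("hsa-mir-", i), 6), blk, "miRNA2gene")
  }
  for (i in 3:10) {
    rec <- add(rec, rep(paste0("TF", i), 6), sample(genes, 6), "TF2gene")
    rec <- add(rec, rep(paste0("hsa-mir-", i), 6), sample(genes, 6),
               "miRNA2gene")
  }
  res <- significant_pairs(reg_network(rec), alpha = 0.05)
  planted <- paste0("TF", 1:2, "|hsa-mir-", 1:2)
  expect_true(all(planted %in% paste(res$tf, res$mirna, sep = "|")))
  expect_true(all(res$x[paste(res$tf, res$mirna, sep = "|") %in% planted] == 6))
})

test_that("motif classification matches the four planted topologies", {
  net <- four_class_net()
  pairs <- significant_pairs(net, all = TRUE)
  motifs <- find_ffl_motifs(net, pairs)
  got <- unique(motifs[, c("motif_type", "tf")])
  expect_equal(got$motif_type[match(paste0("TF", 1:4), got$tf)],
               c("coreg_FFL", "TF_FFL", "miRNA_FFL", "composite_FFL"))
  # classification is exclusive: one class per (tf, mirna, gene) triple
  expect_equal(anyDuplicated(motifs[, c("tf", "mirna", "gene")]), 0L)
  expect_equal(unname(count_motifs(motifs)), rep(3L, 4))
})

test_that("motif scan equals brute-force triple enumeration on random nets", {
  set.seed(17)
  n_done <- 0
  while (n_done < 25) {
    net <- random_network(n_tf = 4, n_gene = 9, n_mir = 4)
    if (is.null(net) || igraph::vcount(net) > 30) next
    pairs <- suppressWarnings(significant_pairs(net, all = TRUE))
    if (!nrow(pairs)) next
    got <- sort_df(find_ffl_motifs(net, pairs))
    want <- sort_df(oracle_triples(net, pairs))
    expect_equal(got, want)
    n_done <- n_done + 1
  }
})

test_that("motif scan errors when a pair is missing from the network", {
  net <- four_class_net()
  fake <- data.frame(tf = "TFX", mirna = "hsa-mir-1", stringsAsFactors = FALSE)
  expect_error(find_ffl_motifs(net, fake), "not present")
})

test_that("randomization preserves per-node, per-type in/out degrees", {
  set.seed(41)
  for (seed in c(1, 2, 3)) {
    net <- random_network(n_tf = 5, n_gene = 12, n_mir = 5)
    rnd <- degree_preserving_randomize(net, seed = seed)
    ed0 <- network_edges(net); ed1 <- network_edges(rnd)
    for (tp in unique(ed0$interaction_type)) {
      a <- ed0[ed0$interaction_type == tp, ]; b <- ed1[ed1$interaction_type == tp, ]
      expect_equal(table(a$from), table(b$from))
      expect_equal(table(a$to), table(b$to))
    }
    # node classes unchanged
    expect_equal(sort_df(network_nodes(rnd)), sort_df(network_nodes(net)))
    # no duplicate edges, no self loops
    expect_equal(anyDuplicated(ed1[, c("from", "to", "interaction_type")]), 0L)
    expect_true(all(ed1$from != ed1$to))
  }
})

test_that("a two-edge network with no legal swap is returned unchanged", {
  rec <- data.frame(regulator = c("TF1", "TF1"), target = c("G1", "G2"),
                    interaction_type = "TF2gene", evidence = "validated",
                    source = "t", stringsAsFactors = FALSE)
  net <- reg_network(rec)
  rnd <- degree_preserving_randomize(net, seed = 1)
  expect_equal(sort_df(network_edges(rnd)), sort_df(network_edges(net)))
})

test_that("randomization with a fixed seed is reproducible", {
  set.seed(9)
  net <- random_network(n_tf = 5, n_gene = 12, n_mir = 5)
  r1 <- degree_preserving_randomize(net, seed = 77)
  r2 <- degree_preserving_randomize(net, seed = 77)
  expect_equal(sort_df(network_edges(r1)), sort_df(network_edges(r2)))
})

test_that("motif significance report is seed-reproducible and coherent", {
  st <- generate_study(synth_config(seed = 2))
  net <- build_combined_network(st$db, st$dereg$genes, st$dereg$mirnas)
  ms1 <- motif_significance(net, n_networks = 15, seed = 5)
  ms2 <- motif_significance(net, n_networks = 15, seed = 5)
  expect_identical(ms1, ms2)
  expect_equal(ms1$empirical_p, ms1$N_h / ms1$N_r)
  ok <- ms1$sigma > 0
  expect_equal(ms1$zscore[ok], (ms1$N_o[ok] - ms1$N_m[ok]) / ms1$sigma[ok])
  expect_true(all(is.na(ms1$zscore[!ok])))
  expect_true(all(ms1$empirical_p_smoothed > 0))
  expect_error(motif_significance(net, n_networks = 0), "n_networks")
})

test_that("randomization summary formulas reproduce hand-worked values", {
  expect_equal(motif_zscore(10, 4, 2), 3.0)
  expect_equal(motif_empirical_p(5, 100), 0.05)
  expect_true(is.na(motif_zscore(7, 7, 0)))
})
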