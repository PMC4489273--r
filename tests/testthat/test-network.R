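test_that("combined network keeps exactly the edges with both endpoints deregulated", {
  db <- interaction_db(toy_records())
  net <- build_combined_network(db, genes = c("G1", "TF1"),
                                mirnas = "hsa-mir-1")
  ed <- network_edges(net)
  expect_setequal(paste(ed$from, ed$to),
                  c("TF1 G1", "TF1 hsa-mir-1", "hsa-mir-1 G1"))
  # TF2 -> G2 absent: G2 not deregulated
  expect_false("TF2" %in% network_nodes(net)$name)
})

test_that("combined network membership matches a brute-force edge scan", {
  set.seed(8)
  for (rep in 1:5) {
    rec <- random_records(n_tf = 5, n_gene = 12, n_mir = 5)
    db <- interaction_db(rec)
    genes <- sample(c(paste0("G", 1:12), paste0("TF", 1:5)), 10)
    mirnas <- sample(paste0("hsa-mir-", 1:5), 3)
    net <- suppressWarnings(build_combined_network(db, genes, mirnas))
    ok <- function(id, cls) if (cls == "miRNA") id %in% mirnas else id %in% genes
    keep <- mapply(function(r, rc, t, tc) ok(r, rc) && ok(t, tc),
                   db$records$regulator, db$records$regulator_class,
                   db$records$target, db$records$target_class)
    expect_equal(igraph::ecount(net), sum(keep))
    # no endpoint outside the deregulated sets
    nd <- network_nodes(net)
    expect_true(all(nd$name[nd$node_class == "miRNA"] %in% mirnas))
    expect_true(all(nd$name[nd$node_class != "miRNA"] %in% genes))
  }
})

test_that("node classes come from the database: TFs stay TFs in subnetworks", {
  db <- interaction_db(toy_records())
  net <- build_combined_network(db, genes = c("G1", "TF1"),
                                mirnas = "hsa-mir-1")
  nd <- network_nodes(net)
  expect_equal(nd$node_class[nd$name == "TF1"], "TF")
  expect_equal(nd$node_class[nd$name == "G1"], "gene")
  expect_equal(nd$node_class[nd$name == "hsa-mir-1"], "miRNA")
})

test_that("miRNA inference requires both target and TF enrichment", {
  # planted miRNA: 5 targets all inside a 10-gene deregulated set drawn
  # from a 1000-gene universe, and its regulator TF deregulated too
  rec <- data.frame(
    regulator = c(rep("hsa-mir-1", 5), rep("hsa-mir-2", 5),
                  "TF1", "TF1b", "TF2", "TF1", "TF1b"),
    target = c(paste0("G", 1:5), paste0("G", 500:504),
               "hsa-mir-1", "hsa-mir-1", "hsa-mir-2", "G1", "G2"),
    interaction_type = c(rep("miRNA2gene", 10), rep("TF2miRNA", 3),
                         rep("TF2gene", 2)),
    evidence = "validated", source = "t", stringsAsFactors = FALSE)
  # pad the gene universe to 1000 and the TF universe to 20
  pad <- rbind(
    data.frame(regulator = "hsa-mir-99", target = paste0("G", 1:1000),
               interaction_type = "miRNA2gene", evidence = "validated",
               source = "pad", stringsAsFactors = FALSE),
    data.frame(regulator = paste0("TF", 3:19), target = "G999",
               interaction_type = "TF2gene", evidence = "validated",
               source = "pad", stringsAsFactors = FALSE))
  db <- interaction_db(rbind(rec, pad))
  dereg <- c(paste0("G", 1:9), "TF1", "TF1b")
  res <- infer_mirnas(db, dereg, alpha = 0.05)
  d1 <- res$detail[res$detail$mirna == "hsa-mir-1", ]
  # test (a) oracle: all 5 targets hit in N=9 dereg genes of M=1000
  expect_equal(d1$p_target, oracle_hyper_tail(5, 5, 9, 1000))
  expect_true("hsa-mir-1" %in% res$mirnas)
  # hsa-mir-2: zero targets deregulated -> never returned
  expect_false("hsa-mir-2" %in% res$mirnas)
})

test_that("miRNA inference is monotone in alpha", {
  st <- generate_study(synth_config(seed = 3))
  lo <- infer_mirnas(st$db, st$dereg$genes, alpha = 1e-6)
  mid <- infer_mirnas(st$db, st$dereg$genes, alpha = 0.001)
  hi <- infer_mirnas(st$db, st$dereg$genes, alpha = 0.5)
  expect_true(all(lo$mirnas %in% mid$mirnas))
  expect_true(all(mid$mirnas %in% hi$mirnas))
})

test_that("disease subnetwork keeps edges with at least one associated endpoint", {
  db <- interaction_db(toy_records())
  net <- build_combined_network(db, genes = c("G1", "G2", "TF1", "TF2"),
                                mirnas = c("hsa-mir-1", "hsa-mir-2"))
  assoc <- disease_associations("toy disease", genes = "G1")
  sub <- extract_disease_network(net, assoc)
  ed <- network_edges(sub)
  expect_setequal(paste(ed$from, ed$to), c("TF1 G1", "hsa-mir-1 G1"))
  # subgraph property
  expect_true(all(paste(ed$from, ed$to) %in%
                    paste(network_edges(net)$from, network_edges(net)$to)))
})

test_that("disease extraction matches a brute-force edge scan on random nets", {
  set.seed(19)
  for (rep in 1:5) {
    net <- random_network(n_tf = 5, n_gene = 10, n_mir = 5)
    nd <- network_nodes(net)$name
    picked <- sample(nd, 4)
    assoc <- disease_associations("d", genes = picked[!is_mirna_id(picked)],
                                  mirnas = picked[is_mirna_id(picked)])
    sub <- suppressWarnings(extract_disease_network(net, assoc))
    ed <- network_edges(net)
    expect_equal(igraph::ecount(sub),
                 sum(ed$from %in% picked | ed$to %in% picked))
    # node set = endpoints of retained edges only
    keep <- ed[ed$from %in% picked | ed$to %in% picked, ]
    expect_setequal(network_nodes(sub)$name, unique(c(keep$from, keep$to)))
  }
})

test_that("coverage ratio follows the node and edge count formulas", {
  db <- interaction_db(toy_records())
  net <- build_combined_network(db, genes = c("G1", "G2", "TF1", "TF2"),
                                mirnas = c("hsa-mir-1", "hsa-mir-2"))
  cov <- coverage_ratio(net, net)
  expect_equal(cov$node_CR, 1)
  expect_equal(cov$edge_CR, 1)

  sub <- extract_disease_network(net, disease_associations("d", genes = "G1"))
  cov2 <- coverage_ratio(sub, net)
  expect_equal(cov2$node_CR, cov2$N_d / cov2$N_t)
  expect_equal(cov2$edge_CR, cov2$E_d / cov2$E_t)

  # a non-subgraph signals an upstream bug
  other <- reg_network(data.frame(regulator = "TFX", target = "GX",
                                  interaction_type = "TF2gene",
                                  evidence = "validated", source = "x"))
  expect_error(coverage_ratio(other, net), "subgraph")
})

test_that("degree distribution sums to node count and handles degenerate nets", {
  rec <- data.frame(regulator = c("TF1", "TF2"), target = c("G1", "G1"),
                    interaction_type = "TF2gene", evidence = "validated",
                    source = "t", stringsAsFactors = FALSE)
  # path TF1 -> G1 <- TF2: total degrees {1, 1, 2}
  dd <- degree_distribution_table(reg_network(rec))
  expect_equal(dd, data.frame(degree = 1:2, count = c(2L, 1L)))
  empty <- reg_network(rec[0, ])
  expect_equal(nrow(degree_distribution_table(empty)), 0L)
  set.seed(4)
  net <- random_network()
  for (m in c("total", "in", "out"))
    expect_equal(sum(degree_distribution_table(net, m)$count),
                 igraph::vcount(net))
})

test_that("overlap report matches exact enumeration on a small fixture", {
  # universe 50, k = 10 db targets, N = 10 dereg targets, overlap 5
  rec <- data.frame(regulator = "TF1", target = paste0("G", 1:10),
                    interaction_type = "TF2gene", evidence = "validated",
                    source = "t", stringsAsFactors = FALSE)
  pad <- data.frame(regulator = "TF2", target = paste0("G", 1:50),
                    interaction_type = "TF2gene", evidence = "validated",
                    source = "pad", stringsAsFactors = FALSE)
  db <- interaction_db(rbind(rec, pad))
  dereg_targets <- paste0("G", 6:15)  # overlap with TF1 targets = G6..G10
  rep <- overlap_report(db, "TF2gene", dereg_regulators = "TF1",
                        dereg_targets = dereg_targets, n_random = 50,
                        seed = 2)
  expect_equal(rep$n_overlap, 5L)
  expect_equal(rep$hypergeom_p, oracle_hyper_tail(5, 10, 10, 50))
  expect_true(rep$randomization_p > 0 && rep$randomization_p <= 1)
})

test_that("overlap randomization P is smallest when the overlap is maximal", {
  rec <- data.frame(regulator = c(rep("TF1", 4), rep("TF2", 4)),
                    target = c(paste0("G", 1:4), paste0("G", 21:24)),
                    interaction_type = "TF2gene", evidence = "validated",
                    source = "t", stringsAsFactors = FALSE)
  db <- interaction_db(rec)
  rep <- overlap_report(db, "TF2gene", "TF1", paste0("G", 1:4),
                        n_random = 100, seed = 1)
  # observed overlap is the maximum possible for TF1's target set
  expect_equal(rep$n_overlap, 4L)
  # disjoint dereg targets give hypergeometric P = 1 (x = 0, inclusive tail)
  rep0 <- overlap_report(db, "TF2gene", "TF1", paste0("X", 1:5),
                         n_random = 20, seed = 1)
  expect_equal(rep0$hypergeom_p, 1)
  expect_error(overlap_report(db, "miRNA2gene", "m", "g"), "no regulators")
})
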