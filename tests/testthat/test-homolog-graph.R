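# Candidate graph construction, distance pruning, cluster joining and graph
# comparison.

base_seq <- "GGTTCCGTAGTGTAGTGGTTATCACGTTCGCCTAACACGCGAAAGGTCCCCGGTTCGAAACCGGGCGGAAACA"

mk_genes <- function(sp, ids, starts, seqs, anticodon = "AGT") {
  trna_genes(ids, sp, "chr1", starts, starts + nchar(seqs),
             sequence = seqs, anticodon = anticodon)
}

test_that("mutually enclosed genes get candidate edges, others do not", {
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 500, 1000), species)
  genes <- rbind(
    mk_genes("a", "a1", 200, base_seq),
    mk_genes("b", "b1", 250, base_seq),
    mk_genes("b", "b2", 700, base_seq))  # beyond the shared right anchor
  g <- build_candidate_graph(genes, anchors)
  expect_equal(g$edges, data.frame(from = "a1", to = "b1",
                                   stringsAsFactors = FALSE))
  expect_equal(g$stage, "candidate")
})

test_that("a query gene gains edges to exactly the enclosed target loci", {
  # one gene in species a between anchors; three loci of species b enclosed
  # by the same tight pair, one outside
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 1000, 2000), species)
  genes <- rbind(
    mk_genes("a", "t", 500, base_seq),
    mk_genes("b", c("x1", "x2", "x3"), c(150, 400, 800),
             c(base_seq, base_seq, base_seq)),
    mk_genes("b", "y", 1500, base_seq))
  g <- build_candidate_graph(genes, anchors)
  nb <- sort(c(g$edges$to[g$edges$from == "t"], g$edges$from[g$edges$to == "t"]))
  expect_equal(nb, c("x1", "x2", "x3"))
})

test_that("genes flagged missing stay as singletons outside cluster edges", {
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 1000), species)
  genes <- rbind(
    mk_genes("a", "a1", 400, base_seq),
    mk_genes("a", "a2", 1200, base_seq),  # right of the last anchor
    mk_genes("b", "b1", 400, base_seq))
  g <- build_candidate_graph(genes, anchors)
  expect_false("a2" %in% c(g$edges$from, g$edges$to))
  cl <- g$clusters
  expect_equal(cl$flag[cl$gene_id == "a2"], "missing")
  expect_match(cl$cluster_id[cl$gene_id == "a2"], "orphan")
})

test_that("pruning keeps similar and remolded genes, removes distinct ones", {
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 1000), species)
  s_ident <- base_seq                       # identical
  s_far <- mutate_k(base_seq, 10)           # 10/73 ~ 13.7 %
  s_ac <- mutate_k(base_seq, 3, pos = 35:37)  # anticodon-only change ~4 %
  genes <- rbind(
    mk_genes("a", c("a1", "a2", "a3"), c(100, 300, 500),
             c(base_seq, base_seq, base_seq)),
    mk_genes("b", c("b1", "b2", "b3"), c(100, 300, 500),
             c(s_ident, s_far, s_ac)))
  g <- build_candidate_graph(genes, anchors)
  p <- prune_by_distance(g, distance_params(0.10))
  keys <- paste(p$edges$from, p$edges$to)
  expect_true("a1 b1" %in% keys)            # identical: kept
  expect_false(any(grepl("b2", keys)))      # 13.7 %: removed everywhere
  expect_true("a1 b3" %in% keys)            # remolding candidate: kept
  # spanning subgraph + idempotence
  expect_equal(nrow(graph_compare(p, g)$only_g1), 0)
  expect_identical(prune_by_distance(p, distance_params(0.10))$edges, p$edges)
})

test_that("hamming metric demands equal lengths and counts mismatches", {
  expect_equal(seq_distance("ACGT", "ACGA", "hamming"), 0.25)
  expect_error(seq_distance("ACGT", "ACG", "hamming"), "unequal")
  expect_equal(seq_distance("ACGT", "ACGTT", "edit"), 1 / 4.5)
})

test_that("same-species edges are rejected at construction", {
  genes <- mk_genes("a", c("a1", "a2"), c(0, 100), c(base_seq, base_seq))
  expect_error(
    orthology_graph(genes, data.frame(from = "a1", to = "a2"), "candidate"),
    "same species")
})

test_that("joining merges clusters sharing boundary anchors transitively", {
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 500, 1000, 1500), species)
  genes <- rbind(
    mk_genes("a", c("a1", "a2", "a3"), c(200, 700, 1200),
             c(base_seq, base_seq, base_seq)),
    mk_genes("b", c("b1", "b2", "b3"), c(200, 700, 1200),
             c(base_seq, base_seq, base_seq)))
  g <- build_candidate_graph(genes, anchors)
  expect_equal(length(unique(g$clusters$cluster_id)), 3)
  j <- join_components(g)
  # chain A1|A2, A2|A3, A3|A4 collapses into one cluster
  expect_equal(length(unique(j$clusters$cluster_id)), 1)
  expect_identical(j$edges, g$edges)
  n_comp <- function(x) length(unique(graph_components(x)$component))
  expect_lte(n_comp(j), n_comp(g))
})

test_that("joining leaves clusters with disjoint boundaries alone", {
  species <- c("a", "b")
  anchors <- rbind(shared_anchors(c(0, 500), species),
                   anchor_table(c("B1", "B1", "B2", "B2"), rep(species, 2),
                                "chr2", c(0, 0, 500, 500), c(10, 10, 510, 510)))
  genes <- rbind(
    mk_genes("a", "a1", 200, base_seq),
    mk_genes("b", "b1", 200, base_seq))
  genes2 <- rbind(
    trna_genes("a2", "a", "chr2", 200, 273, sequence = base_seq),
    trna_genes("b2", "b", "chr2", 200, 273, sequence = base_seq))
  g <- build_candidate_graph(rbind(genes, genes2), anchors)
  expect_equal(length(unique(g$clusters$cluster_id)), 2)
  expect_equal(length(unique(join_components(g)$clusters$cluster_id)), 2)
})

test_that("graph comparison matches brute-force set operations", {
  cmp <- graph_compare(data.frame(from = "a1", to = "b1"),
                       data.frame(from = "a1", to = "b1"))
  expect_equal(cmp$symmetric_difference, 0)
  cmp2 <- graph_compare(data.frame(from = "a1", to = "b1"),
                        data.frame(from = c("a1", "c1"), to = c("b1", "d1")))
  expect_equal(nrow(cmp2$shared), 1)
  expect_equal(cmp2$only_g2$from, "c1")
  set.seed(5)
  verts_a <- paste0("a", 1:5); verts_b <- paste0("b", 1:5)
  all_pairs <- expand.grid(from = verts_a, to = verts_b,
                           stringsAsFactors = FALSE)
  for (rep_i in 1:10) {
    e1 <- all_pairs[sample(nrow(all_pairs), 8), ]
    e2 <- all_pairs[sample(nrow(all_pairs), 8), ]
    cmp <- graph_compare(e1, e2)
    k1 <- paste(e1$from, e1$to); k2 <- paste(e2$from, e2$to)
    expect_equal(nrow(cmp$shared), length(intersect(k1, k2)))
    expect_equal(cmp$symmetric_difference,
                 length(setdiff(k1, k2)) + length(setdiff(k2, k1)))
  }
})

test_that("inversion-tolerant mode accepts order-reversed anchor placements", {
  # anchors A1, A2 appear in opposite order in species b
  anchors <- anchor_table(
    c("A1", "A1", "A2", "A2"), rep(c("a", "b"), 2), "chr1",
    c(0, 1000, 1000, 0), c(10, 1010, 1010, 10))
  genes <- rbind(
    mk_genes("a", "a1", 500, base_seq),
    mk_genes("b", "b1", 500, base_seq))
  g_strict <- build_candidate_graph(genes, anchors, allow_inversions = FALSE)
  g_relax <- build_candidate_graph(genes, anchors, allow_inversions = TRUE)
  expect_equal(nrow(g_strict$edges), 0)
  expect_equal(nrow(g_relax$edges), 1)
})
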