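# Duplication-aware list alignment and the estimated orthology graph.

P <- scoring_params()  # match 20, gap 25, eta 3, q_max 2

test_that("scoring invariants are enforced", {
  expect_error(scoring_params(dup_penalty = 0), "dup_penalty")
  expect_error(scoring_params(match_cost = 60, gap_cost = 25), "twice")
  expect_error(scoring_params(match_cost = 20, gap_cost = 21), "cheaper")
})

test_that("elementary alignments have the expected costs and columns", {
  sim <- matrix(20, 1, 1)
  a <- align_lists("x", "y", sim, P)
  expect_equal(a$cost, 20)
  expect_equal(a$columns$type, "match")

  e <- align_lists(character(0), character(0), matrix(0, 0, 0), P)
  expect_equal(e$cost, 0)
  expect_equal(nrow(e$columns), 0)

  # one gene vs two similar copies: duplication column beats match + gap
  d <- align_lists("x", c("y1", "y2"), matrix(20, 1, 2), P)
  expect_equal(d$cost, 43)
  expect_equal(d$columns$type, "dup")
  expect_equal(d$columns$b_ids, "y1,y2")

  # dissimilar pair: two gaps
  g <- align_lists("x", "y", matrix(Inf, 1, 1), P)
  expect_equal(g$cost, 50)
  expect_setequal(g$columns$type, c("a_only", "b_only"))
})

test_that("alignment cost equals exhaustive enumeration on random lists", {
  set.seed(101)
  for (rep_i in 1:60) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    delta <- matrix(sample(c(20, Inf), n * m, replace = TRUE, prob = c(.6, .4)),
                    n, m)
    got <- align_lists(sprintf("a%d", seq_len(n)), sprintf("b%d", seq_len(m)),
                       delta, P)$cost
    want <- enum_align_cost(delta, P$gap_cost, P$dup_penalty, P$q_max)
    expect_equal(got, want)
    # symmetry
    got_t <- align_lists(sprintf("b%d", seq_len(m)), sprintf("a%d", seq_len(n)),
                         t(delta), P)$cost
    expect_equal(got_t, got)
  }
})

test_that("q_max = 1 with large eta reduces to classical Needleman-Wunsch", {
  set.seed(102)
  P1 <- scoring_params(q_max = 1)
  for (rep_i in 1:20) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    delta <- matrix(sample(c(20, Inf), n * m, replace = TRUE), n, m)
    got <- align_lists(sprintf("a%d", seq_len(n)), sprintf("b%d", seq_len(m)),
                       delta, P1)$cost
    # classical NW oracle (no duplication moves)
    D <- matrix(Inf, n + 1, m + 1)
    D[1, ] <- (0:m) * P1$gap_cost; D[, 1] <- (0:n) * P1$gap_cost
    for (i in 1:n) for (j in 1:m) {
      D[i + 1, j + 1] <- min(D[i, j] + delta[i, j],
                             D[i, j + 1] + P1$gap_cost,
                             D[i + 1, j] + P1$gap_cost)
    }
    expect_equal(got, D[n + 1, m + 1])
    expect_gte(got,
               align_lists(sprintf("a%d", seq_len(n)), sprintf("b%d", seq_len(m)),
                           delta, P)$cost)
  }
})

test_that("alignment consumes both lists exactly once, in order", {
  set.seed(103)
  for (rep_i in 1:20) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    delta <- matrix(sample(c(20, Inf), n * m, replace = TRUE), n, m)
    ids_a <- sprintf("a%d", seq_len(n)); ids_b <- sprintf("b%d", seq_len(m))
    aln <- align_lists(ids_a, ids_b, delta, P)
    got_a <- unlist(strsplit(aln$columns$a_ids[aln$columns$a_ids != ""], ","))
    got_b <- unlist(strsplit(aln$columns$b_ids[aln$columns$b_ids != ""], ","))
    expect_identical(got_a, ids_a)
    expect_identical(got_b, ids_b)
    # cost equals the sum of column costs
    colcost <- apply(aln$columns, 1, function(r) {
      na <- length(strsplit(r[["a_ids"]], ",")[[1]])
      nb <- length(strsplit(r[["b_ids"]], ",")[[1]])
      if (r[["type"]] %in% c("a_only", "b_only")) return(P$gap_cost)
      ia <- match(strsplit(r[["a_ids"]], ",")[[1]], ids_a)
      ib <- match(strsplit(r[["b_ids"]], ",")[[1]], ids_b)
      sum(delta[ia, ib]) + (max(na, nb) - 1) * P$dup_penalty
    })
    if (is.finite(aln$cost)) expect_equal(sum(colcost), aln$cost)
  }
})

base_seq <- "GGTTCCGTAGTGTAGTGGTTATCACGTTCGCCTAACACGCGAAAGGTCCCCGGTTCGAAACCGGGCGGAAACA"

toy_pruned <- function(genes, anchors) {
  prune_by_distance(build_candidate_graph(genes, anchors), distance_params())
}

test_that("superimposed alignments produce the estimated orthology graph", {
  species <- c("a", "b", "c")
  anchors <- shared_anchors(c(0, 1000), species)
  genes <- do.call(rbind, lapply(species, function(sp) {
    trna_genes(paste0(sp, "1"), sp, "chr1", 400, 473, sequence = base_seq,
               anticodon = "AGT")
  }))
  est <- build_estimated_orthology(toy_pruned(genes, anchors))
  # one similar gene per species -> triangle component
  expect_equal(nrow(est$graph$edges), 3)
  expect_equal(est$graph$stage, "estimated")

  # 1:2 duplication column yields both co-orthology edges
  genes2 <- rbind(
    trna_genes("x", "a", "chr1", 400, 473, sequence = base_seq),
    trna_genes(c("y1", "y2"), "b", "chr1", c(300, 500), c(373, 573),
               sequence = base_seq))
  est2 <- build_estimated_orthology(toy_pruned(genes2, anchors))
  expect_setequal(paste(est2$graph$edges$from, est2$graph$edges$to),
                  c("x y1", "x y2"))
  expect_true("dup" %in% est2$alignments$type)

  # two separate clusters -> two components
  anchors3 <- shared_anchors(c(0, 1000, 2000), c("a", "b"))
  genes3 <- rbind(
    trna_genes(c("a1", "a2"), "a", "chr1", c(400, 1400), c(473, 1473),
               sequence = base_seq),
    trna_genes(c("b1", "b2"), "b", "chr1", c(400, 1400), c(473, 1473),
               sequence = base_seq))
  est3 <- build_estimated_orthology(toy_pruned(genes3, anchors3))
  comp <- graph_components(est3$graph, use_clusters = FALSE)
  expect_equal(length(unique(comp$component)), 2)
})

test_that("estimated components restricted to two species never cross", {
  set.seed(104)
  species <- c("a", "b", "c")
  anchors <- shared_anchors(c(0, 5000), species)
  for (rep_i in 1:5) {
    fam <- replicate(3, random_dna(73))
    rows <- list()
    for (sp in species) {
      ng <- sample(3:6, 1)
      fidx <- sort(sample(1:3, ng, replace = TRUE))
      st <- seq(300, by = 300, length.out = ng)
      rows[[sp]] <- trna_genes(paste0(sp, seq_len(ng)), sp, "chr1",
                               st, st + 73,
                               sequence = vapply(fidx, function(i)
                                 mutate_k(fam[i], sample(0:1, 1)), ""))
    }
    genes <- do.call(rbind, rows)
    est <- build_estimated_orthology(toy_pruned(genes, anchors))
    pos <- stats::setNames(genes$start, genes$gene_id)
    sp_of <- stats::setNames(genes$species, genes$gene_id)
    comp <- graph_components(est$graph, use_clusters = FALSE)
    for (cid in unique(comp$component)) {
      ids <- comp$gene_id[comp$component == cid]
      e <- est$graph$edges[est$graph$edges$from %in% ids |
                             est$graph$edges$to %in% ids, ]
      if (nrow(e) < 2) next
      for (i in 1:(nrow(e) - 1)) for (j in (i + 1):nrow(e)) {
        p1 <- c(e$from[i], e$to[i]); p2 <- c(e$from[j], e$to[j])
        if (!setequal(sp_of[p1], sp_of[p2]) || length(unique(sp_of[p1])) != 2) next
        a1 <- p1[order(sp_of[p1])]; a2 <- p2[order(sp_of[p2])]
        # same species pair: strictly crossing edge pairs are forbidden
        # (shared endpoints, e.g. from duplication columns, do not cross)
        expect_false((pos[a1[1]] - pos[a2[1]]) * (pos[a1[2]] - pos[a2[2]]) < 0)
      }
    }
  }
})
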