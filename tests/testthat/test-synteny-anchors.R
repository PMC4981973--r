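# Synteny anchors: block cleaning, protein anchors, tight anchor pairs and
# coordinate interpolation.

test_that("overlapping blocks and tRNA-overlapping blocks are removed", {
  blocks <- data.frame(
    block_id = rep(c("A", "B", "C", "D"), each = 2),
    species = rep(c("a", "b"), 4),
    chrom = "chr1",
    start = c(0, 0, 20, 20, 25, 25, 40, 40),
    end = c(10, 10, 30, 30, 35, 35, 50, 50),
    strand = "+", stringsAsFactors = FALSE)
  trna <- data.frame(species = "a", chrom = "chr1", start = 42, end = 46,
                     stringsAsFactors = FALSE)
  out <- clean_maf_blocks(blocks, trna)
  # B and C mutually overlap, D overlaps the tRNA; only A survives
  expect_setequal(unique(out$anchor_id), "A")

  # nothing to filter: both blocks kept, sorted
  out2 <- clean_maf_blocks(blocks[blocks$block_id %in% c("A", "D"), ], NULL)
  expect_setequal(unique(out2$anchor_id), c("A", "D"))

  expect_equal(nrow(clean_maf_blocks(blocks[0, ], trna)), 0)
})

test_that("cleaned blocks are pairwise disjoint in every species", {
  set.seed(42)
  for (rep_i in 1:10) {
    n <- 30
    st <- sample(0:500, n)
    blocks <- data.frame(
      block_id = rep(sprintf("B%02d", 1:n), each = 2),
      species = rep(c("a", "b"), n),
      chrom = "chr1",
      start = rep(st, each = 2),
      end = rep(st + sample(5:40, n, replace = TRUE), each = 2),
      strand = "+", stringsAsFactors = FALSE)
    out <- clean_maf_blocks(blocks, NULL)
    for (sp in c("a", "b")) {
      b <- out[out$species == sp, ]
      b <- b[order(b$start), ]
      if (nrow(b) > 1) expect_true(all(b$end[-nrow(b)] <= b$start[-1]))
    }
  }
})

test_that("malformed block spans are rejected with a warning, not an error", {
  blocks <- data.frame(
    block_id = rep(c("A", "B"), each = 2),
    species = rep(c("a", "b"), 2), chrom = "chr1",
    start = c(0, 0, 50, 60), end = c(10, 10, 55, 40),  # B inconsistent in b
    strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- clean_maf_blocks(blocks, NULL), "inconsistent")
  expect_setequal(unique(out$anchor_id), "A")
})

test_that("protein pairs are chain-filtered and reduced to 1:1", {
  mkpair <- function(ida, sa, ea, idb, sb, eb) {
    data.frame(id_a = ida, species_a = "a", chrom_a = "chr1",
               start_a = sa, end_a = ea,
               id_b = idb, species_b = "b", chrom_b = "chr1",
               start_b = sb, end_b = eb, stringsAsFactors = FALSE)
  }
  chain <- data.frame(species_a = "a", chrom_a = "chr1", start_a = 0,
                      end_a = 1000, species_b = "b", chrom_b = "chr1",
                      start_b = 0, end_b = 1000, stringsAsFactors = FALSE)
  # contained pair retained
  out <- filter_protein_orthologs(mkpair("p", 100, 200, "q", 300, 400), chain)
  expect_equal(length(unique(out$anchor_id)), 1)
  # no chain covering b -> dropped
  chain2 <- chain; chain2$end_b <- 350
  out2 <- filter_protein_orthologs(mkpair("p", 100, 200, "q", 300, 400), chain2)
  expect_equal(nrow(out2), 0)
  # many-to-many: only the chain-supported pair survives, still 1:1
  pairs <- rbind(mkpair("p", 100, 200, "q1", 300, 400),
                 mkpair("p", 100, 200, "q2", 1500, 1600))
  out3 <- filter_protein_orthologs(pairs, chain)
  expect_equal(unique(out3$anchor_id), "p~q1")
  # a gene in two chain-supported pairs disappears entirely
  chain_all <- rbind(chain, transform(chain, start_b = 1400, end_b = 2000))
  out4 <- filter_protein_orthologs(pairs, chain_all)
  expect_equal(nrow(out4), 0)
})

test_that("tight anchor pairs skip anchors absent from the target species", {
  # anchors at 10 (in target), 50 (not), 90 (in target); gene at 60
  anchors <- rbind(
    shared_anchors(c(10, 90), c("a", "b")),
    anchor_table("X", c("a", "c"), "chr1", c(50, 50), c(60, 60)))
  gene <- data.frame(species = "a", chrom = "chr1", start = 62, end = 70)
  pr <- tight_anchor_pair(gene, "b", anchors)
  expect_equal(pr$status, "ok")
  expect_equal(pr$left, "A1")
  expect_equal(pr$right, "A2")
  # into species c the anchor at 50 is usable but nothing flanks the right
  pr2 <- tight_anchor_pair(gene, "c", anchors)
  expect_equal(pr2$status, "missing")
  expect_true(is.na(pr2$right))
})

test_that("anchors on different target chromosomes flag a split", {
  anchors <- rbind(
    anchor_table("L", c("a", "b"), c("chr1", "chr1"), c(10, 10), c(20, 20)),
    anchor_table("R", c("a", "b"), c("chr1", "chr2"), c(90, 90), c(100, 100)))
  gene <- data.frame(species = "a", chrom = "chr1", start = 40, end = 50)
  expect_equal(tight_anchor_pair(gene, "b", anchors)$status, "split")
})

test_that("adding anchors never widens a tight anchor pair", {
  set.seed(7)
  species <- c("a", "b")
  pool <- setdiff(seq(0, 1000, by = 20), 500)  # keep anchors off the gene
  gene <- data.frame(species = "a", chrom = "chr1", start = 505, end = 512)
  span <- function(pr, anc) {
    l <- anc[anc$anchor_id == pr$left & anc$species == "a", ]
    r <- anc[anc$anchor_id == pr$right & anc$species == "a", ]
    c(l$end, r$start)
  }
  for (rep_i in 1:20) {
    pos1 <- sort(sample(pool, 6))
    pos2 <- sort(union(pos1, sample(setdiff(pool, pos1), 3)))
    pr1 <- tight_anchor_pair(gene, "b", shared_anchors(pos1, species))
    pr2 <- tight_anchor_pair(gene, "b", shared_anchors(pos2, species))
    if (pr1$status == "ok") {
      expect_equal(pr2$status, "ok")
      s1 <- span(pr1, shared_anchors(pos1, species))
      s2 <- span(pr2, shared_anchors(pos2, species))
      expect_true(s2[1] >= s1[1] && s2[2] <= s1[2])
    }
  }
})

test_that("interpolation reproduces the offset worked example and identity", {
  expect_equal(interpolate_position(1500, 1000, 2000, 500, 1000),
               500 + 501 / 1001 * 500, tolerance = 1e-12)
  # zero offset lands on the left anchor point
  expect_equal(interpolate_position(1000, 1000, 2000, 500, 1000), 500)
  # identical genomes: identity for any position
  for (t in c(120, 555, 900)) {
    expect_equal(interpolate_position(t, 100, 1000, 100, 1000), t)
  }
  expect_error(interpolate_position(5, 10, 10, 0, 5), "span")
})

test_that("interpolation is near-exact under affine coordinate maps", {
  set.seed(11)
  for (rep_i in 1:50) {
    p_a <- sample(0:1000, 1); L <- sample(50:2000, 1); q_a <- p_a + L
    alpha <- stats::runif(1, 0.5, 2); beta <- sample(-500:500, 1)
    p_b <- alpha * p_a + beta; q_b <- alpha * q_a + beta
    t_a <- p_a + sample(0:L, 1)
    t_star <- interpolate_position(t_a, p_a, q_a, p_b, q_b)
    expect_lt(abs(t_star - (alpha * t_a + beta)), 1 + 1e-9)
  }
})

test_that("interpolation orthologs are reciprocal 1:1 and skip co-orthologs", {
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 1000), species)
  mk <- function(sp, ids, starts) {
    trna_genes(ids, sp, "chr1", starts, starts + 70,
               sequence = "ACGT", anticodon = "AAA")
  }
  ga <- mk("a", "a1", 400)
  gb <- mk("b", "b1", 400)
  expect_equal(interpolation_orthologs(ga, gb, anchors),
               data.frame(gene_a = "a1", gene_b = "b1",
                          stringsAsFactors = FALSE))
  # target gene deleted: no pair
  expect_equal(nrow(interpolation_orthologs(ga, gb[0, ], anchors)), 0)
  # two tandem copies in the target: only the closer one is proposed; the
  # 1:2 co-orthology is not representable by interpolation
  gb2 <- mk("b", c("b1", "b2"), c(400, 520))
  out <- interpolation_orthologs(ga, gb2, anchors)
  expect_equal(out$gene_b, "b1")
  expect_lte(nrow(out), 1)
})

test_that("interpolation ortholog sets are partial matchings", {
  set.seed(13)
  species <- c("a", "b")
  anchors <- shared_anchors(c(0, 500, 1000, 1500), species)
  starts <- c(120, 260, 620, 740, 1100, 1320)
  ga <- trna_genes(paste0("a", seq_along(starts)), "a", "chr1",
                   starts, starts + 70)
  gb <- trna_genes(paste0("b", seq_along(starts)), "b", "chr1",
                   starts + sample(-15:15, length(starts), TRUE),
                   starts + 70)
  gb$end <- gb$start + 70
  out <- interpolation_orthologs(ga, gb, anchors)
  expect_lte(max(table(out$gene_a)), 1)
  expect_lte(max(table(out$gene_b)), 1)
})
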