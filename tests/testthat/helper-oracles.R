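# Independent oracles used across the test suite.  These deliberately avoid
# the package's own algorithmic code paths: brute-force enumeration, plain
# combinatorial checks, and closed forms.

# --- generalized list alignment: exhaustive enumeration --------------------
# Minimum cost over all generalized alignments (match / gap / 1:q columns),
# explored by plain recursion over column choices with cost-bound pruning.
enum_align_cost <- function(delta, gap, eta, qmax) {
  n <- nrow(delta); m <- ncol(delta)
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) rec(i + 1, j + 1, acc + delta[i + 1, j + 1])
    if (qmax >= 2) {
      for (q in 2:qmax) {
        if (i < n && j + q <= m) {
          rec(i + 1, j + q, acc + sum(delta[i + 1, (j + 1):(j + q)]) + (q - 1) * eta)
        }
        if (i + q <= n && j < m) {
          rec(i + q, j + 1, acc + sum(delta[(i + 1):(i + q), j + 1]) + (q - 1) * eta)
        }
      }
    }
    if (i < n) rec(i + 1, j, acc + gap)
    if (j < m) rec(i, j + 1, acc + gap)
  }
  rec(0L, 0L, 0)
  best
}

# --- cographs: independent P4 test and exhaustive minimum edit -------------
# On 4 vertices, 3 edges with degree multiset {1,1,2,2} force an induced P4.
oracle_has_p4 <- function(adj) {
  n <- nrow(adj)
  if (n < 4) return(FALSE)
  subs <- utils::combn(n, 4)
  for (k in seq_len(ncol(subs))) {
    s <- subs[, k]
    a <- adj[s, s]
    deg <- unname(rowSums(a))
    if (sum(a) == 6 && identical(sort(deg), c(1, 1, 2, 2))) return(TRUE)
  }
  FALSE
}

# Exhaustive minimum edit size: try all subsets of vertex-pair toggles of
# increasing size until some edited graph is P4-free.
oracle_min_edit <- function(adj, kmax = 6) {
  if (!oracle_has_p4(adj)) return(0L)
  n <- nrow(adj)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  for (k in 1:kmax) {
    sets <- utils::combn(np, k)
    for (c_i in seq_len(ncol(sets))) {
      a2 <- adj
      for (p in sets[, c_i]) {
        u <- pairs[1, p]; v <- pairs[2, p]
        a2[u, v] <- a2[v, u] <- !a2[u, v]
      }
      if (!oracle_has_p4(a2)) return(k)
    }
  }
  NA_integer_
}

adj_from_edges <- function(vertices, edges) {
  n <- length(vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  if (nrow(edges) > 0) {
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj[cbind(edges$to, edges$from)] <- TRUE
  }
  adj
}

edges_from_adj <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  v <- rownames(adj)
  data.frame(from = pmin(v[idx[, 1]], v[idx[, 2]]),
             to = pmax(v[idx[, 1]], v[idx[, 2]]),
             stringsAsFactors = FALSE)
}

# --- random cotrees --------------------------------------------------------
random_cotree <- function(n_leaves, root_label = sample(c("S", "D"), 1),
                          prefix = "g") {
  leaves <- paste0(prefix, seq_len(n_leaves))
  build <- function(ids, label) {
    if (length(ids) == 1) return(list(label = "leaf", gene = ids))
    k <- sample(2:min(length(ids), 4), 1)
    grp <- sample(rep(seq_len(k), length.out = length(ids)))
    kids <- lapply(split(ids, grp), build,
                   label = if (label == "S") "D" else "S")
    node <- list(label = label, children = unname(kids))
    key <- vapply(node$children, function(x) min(cotree_leaves(x)), "")
    node$children <- node$children[order(key)]
    node
  }
  build(leaves, root_label)
}

# --- Dollo parsimony: brute force over all gain placements -----------------
# For each node whose clade contains the leafset, count the maximal subtrees
# below it that contain no observed species; return the minimum.
oracle_dollo <- function(leafset, tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  loss_count <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    total <- 0L
    for (ch in kids) {
      if (any(tips_under(ch) %in% leafset)) total <- total + loss_count(ch)
      else total <- total + 1L
    }
    total
  }
  best <- Inf
  for (node in seq_len(nn)) {
    if (!all(leafset %in% tips_under(node))) next
    l <- loss_count(node)
    if (l < best) best <- l
  }
  best
}

# --- toy data builders -----------------------------------------------------
# A mutated copy of a sequence with exactly k substitutions.
mutate_k <- function(s, k, pos = NULL) {
  ch <- strsplit(s, "")[[1]]
  if (is.null(pos)) pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  paste(ch, collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Anchor table with the same positions in every listed species.
shared_anchors <- function(pos, species, width = 10) {
  anchor_table(
    anchor_id = rep(paste0("A", seq_along(pos)), each = length(species)),
    species = rep(species, times = length(pos)),
    chrom = "chr1",
    start = rep(pos, each = length(species)),
    end = rep(pos + width, each = length(species)))
}
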