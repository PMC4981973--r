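# Generalized list alignment: Needleman-Wunsch over ordered gene lists with
# 1:q / q:1 duplication columns, and its superposition into the estimated
# orthology graph.

#' Scoring parameters for list alignment
#'
#' Costs act on gene-list columns, not nucleotides.  Two similar genes match
#' at `match_cost`; dissimilar genes can never match (infinite cost).  A 1:q
#' duplication column costs the sum of its q pairwise match costs plus
#' `(q-1) * dup_penalty`.  The defaults are constrained so that (i) similar
#' genes prefer a match over two gaps and (ii) a duplication column of
#' similar genes beats a match plus a gap.
#'
#' @param match_cost dissimilarity score of two similar genes (default 20).
#' @param gap_cost cost of leaving a gene unmatched (default 25).
#' @param dup_penalty extra penalty per additional copy in a duplication
#'   column (default 3, must be positive).
#' @param threshold similarity threshold as a fraction of sequence length
#'   (default 0.10): pairs at or above it get infinite cost.
#' @param q_max largest q in a 1:q column (default 2).
#' @export
scoring_params <- function(match_cost = 20, gap_cost = 25, dup_penalty = 3,
                           threshold = 0.10, q_max = 2) {
  stopifnot(dup_penalty > 0, q_max >= 1)
  if (!(match_cost < 2 * gap_cost)) {
    stop("match_cost must be below twice gap_cost (else matches never happen)")
  }
  if (!(2 * match_cost + dup_penalty < match_cost + gap_cost)) {
    stop("duplication column must be cheaper than match plus gap")
  }
  list(match_cost = match_cost, gap_cost = gap_cost,
       dup_penalty = dup_penalty, threshold = threshold, q_max = q_max)
}

#' Pairwise column costs from sequences
#'
#' @param seqs_a,seqs_b character vectors of sequences for the two lists.
#' @param params see [scoring_params()].
#' @param metric distance metric passed to [seq_distance()].
#' @return numeric matrix of `match_cost` / `Inf` values.
#' @export
delta_matrix <- function(seqs_a, seqs_b, params = scoring_params(),
                         metric = "edit") {
  m <- matrix(Inf, length(seqs_a), length(seqs_b))
  for (i in seq_along(seqs_a)) {
    for (j in seq_along(seqs_b)) {
      d <- seq_distance(seqs_a[i], seqs_b[j], metric)
      if (!is.na(d) && d < params$threshold) m[i, j] <- params$match_cost
    }
  }
  m
}

#' Duplication-aware alignment of two ordered gene lists
#'
#' Minimal-cost generalized alignment under the recursion with match,
#' gap and 1:q / q:1 duplication cases.  Traceback ties are broken in the
#' fixed case order match > duplication-in-a > duplication-in-b > gap-in-a >
#' gap-in-b (q ascending within duplications), so output is deterministic.
#'
#' @param ids_a,ids_b character vectors of gene ids, in genomic order.
#' @param delta cost matrix over `ids_a` x `ids_b` (see [delta_matrix()]), or
#'   `NULL` for all-match (useful in tests).
#' @param params see [scoring_params()].
#' @return list with `cost` and `columns`, a `data.frame` with columns
#'   `type` (`"match"`, `"dup"`, `"a_only"`, `"b_only"`), `a_ids`, `b_ids`
#'   (comma-separated id lists).  In a `"dup"` column exactly one side holds
#'   several genes; that side carries the duplication.
#' @export
align_lists <- function(ids_a, ids_b, delta = NULL, params = scoring_params()) {
  n <- length(ids_a); m <- length(ids_b)
  if (is.null(delta)) delta <- matrix(params$match_cost, n, m)
  stopifnot(nrow(delta) == n, ncol(delta) == m)
  gap <- params$gap_cost; eta <- params$dup_penalty; qmax <- params$q_max

  D <- matrix(Inf, n + 1, m + 1)
  # move encoding: consumed (da, db) from each list per column
  mv_a <- matrix(0L, n + 1, m + 1)
  mv_b <- matrix(0L, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) { D[i + 1, 1] <- i * gap; mv_a[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { D[1, j + 1] <- j * gap; mv_b[1, j + 1] <- 1L }

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- Inf; ba <- 0L; bb <- 0L
      consider <- function(cost, da, db) {
        if (cost < best) { best <<- cost; ba <<- da; bb <<- db }
      }
      # M
      consider(D[i, j] + delta[i, j], 1L, 1L)
      # D(a): one gene of a against q genes of b (duplication in b's list)
      for (q in 2:qmax) {
        if (qmax < 2 || j < q) next
        lam <- sum(delta[i, (j - q + 1):j]) + (q - 1) * eta
        consider(D[i, j - q + 1] + lam, 1L, q)
      }
      # D(b): q genes of a against one gene of b
      for (q in 2:qmax) {
        if (qmax < 2 || i < q) next
        lam <- sum(delta[(i - q + 1):i, j]) + (q - 1) * eta
        consider(D[i - q + 1, j] + lam, q, 1L)
      }
      # I(a), I(b): gaps
      consider(D[i, j + 1] + gap, 1L, 0L)
      consider(D[i + 1, j] + gap, 0L, 1L)
      D[i + 1, j + 1] <- best
      mv_a[i + 1, j + 1] <- ba
      mv_b[i + 1, j + 1] <- bb
    }
  }

  cols <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    da <- mv_a[i + 1, j + 1]; db <- mv_b[i + 1, j + 1]
    aid <- if (da > 0) ids_a[(i - da + 1):i] else character(0)
    bid <- if (db > 0) ids_b[(j - db + 1):j] else character(0)
    type <- if (da == 1 && db == 1) "match"
            else if (da >= 1 && db >= 1) "dup"
            else if (da >= 1) "a_only" else "b_only"
    cols[[length(cols) + 1]] <- data.frame(
      type = type,
      a_ids = paste(aid, collapse = ","),
      b_ids = paste(bid, collapse = ","),
      stringsAsFactors = FALSE)
    i <- i - da; j <- j - db
  }
  columns <- if (length(cols)) do.call(rbind, rev(cols)) else
    data.frame(type = character(0), a_ids = character(0),
               b_ids = character(0), stringsAsFactors = FALSE)
  list(cost = D[n + 1, m + 1], columns = columns)
}

# Edges implied by one alignment: match edges plus the complete bipartite
# edges of every duplication column.
alignment_edges <- function(aln) {
  cols <- aln$columns[aln$columns$type %in% c("match", "dup"), , drop = FALSE]
  if (nrow(cols) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(cols)), function(k) {
    a <- strsplit(cols$a_ids[k], ",", fixed = TRUE)[[1]]
    b <- strsplit(cols$b_ids[k], ",", fixed = TRUE)[[1]]
    expand.grid(from = a, to = b, stringsAsFactors = FALSE)
  })
  canonical_edges(do.call(rbind, out))
}

#' Estimated orthology graph from pairwise list alignments
#'
#' Every synteny cluster is aligned between each pair of species that it
#' covers; match columns contribute their edge and duplication columns
#' contribute all edges of their complete bipartite graph.  Match costs are
#' derived from the pruned graph (`match_cost` where the pruned graph has an
#' edge, infinite otherwise), so the result is a spanning subgraph of the
#' pruned graph by construction; any alignment edge not present there would
#' signal a scoring mismatch and is dropped with a warning.
#'
#' @param g_pruned `orthology_graph` at stage `"pruned"`.
#' @param params see [scoring_params()].
#' @return list with `graph` (stage `"estimated"`) and `alignments`, a
#'   `data.frame` log of all alignment columns (cluster, species pair, type,
#'   members, cost).
#' @export
build_estimated_orthology <- function(g_pruned, params = scoring_params()) {
  genes <- g_pruned$genes
  pe <- paste(g_pruned$edges$from, g_pruned$edges$to)
  edge_ok <- function(u, v) paste(pmin(u, v), pmax(u, v)) %in% pe
  edges <- list(); logs <- list()
  cl <- g_pruned$clusters
  for (cid in unique(cl$cluster_id)) {
    members <- genes[genes$gene_id %in% cl$gene_id[cl$cluster_id == cid], , drop = FALSE]
    spp <- sort(unique(members$species))
    if (length(spp) < 2) next
    for (ai in seq_len(length(spp) - 1)) {
      for (bi in (ai + 1):length(spp)) {
        la <- members[members$species == spp[ai], , drop = FALSE]
        lb <- members[members$species == spp[bi], , drop = FALSE]
        la <- la[order(la$start), , drop = FALSE]
        lb <- lb[order(lb$start), , drop = FALSE]
        delta <- matrix(Inf, nrow(la), nrow(lb))
        for (i in seq_len(nrow(la))) {
          ok <- edge_ok(rep(la$gene_id[i], nrow(lb)), lb$gene_id)
          delta[i, ok] <- params$match_cost
        }
        aln <- align_lists(la$gene_id, lb$gene_id, delta, params)
        if (nrow(aln$columns) > 0) {
          logs[[length(logs) + 1]] <- cbind(
            cluster_id = cid, species_a = spp[ai], species_b = spp[bi],
            aln$columns, cost = aln$cost)
        }
        edges[[length(edges) + 1]] <- alignment_edges(aln)
      }
    }
  }
  E <- canonical_edges(if (length(edges)) do.call(rbind, edges) else NULL)
  if (nrow(E) > 0) {
    inpruned <- paste(E$from, E$to) %in% pe
    if (any(!inpruned)) {
      warning(sprintf("%d alignment edge(s) absent from the pruned graph; dropped",
                      sum(!inpruned)))
      E <- E[inpruned, , drop = FALSE]
    }
  }
  list(
    graph = orthology_graph(genes, E, "estimated", g_pruned$clusters),
    alignments = if (length(logs)) do.call(rbind, logs) else NULL
  )
}
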