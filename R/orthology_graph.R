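# Staged homology graph over tRNA genes: candidate -> pruned -> estimated ->
# edited.  Edges always connect genes of different species; genes flanked by
# the same anchor pair additionally share a synteny cluster, and connected
# components are taken over edges plus co-cluster membership so that
# single-species clusters exist as objects.

#' Construct an orthology graph
#'
#' @param genes gene table (see [trna_genes()]).
#' @param edges `data.frame` with columns `from`, `to` (gene ids; stored with
#'   `from < to`).
#' @param stage one of `"candidate"`, `"pruned"`, `"estimated"`, `"edited"`,
#'   `"true"`.
#' @param clusters `data.frame` with columns `gene_id`, `cluster_id`, `flag`
#'   (`"ok"`, `"missing"`, `"split"`), `left_anchor`, `right_anchor`.
#' @return an object of class `orthology_graph`.
#' @export
orthology_graph <- function(genes, edges, stage, clusters = NULL) {
  edges <- canonical_edges(edges)
  sp <- stats::setNames(genes$species, genes$gene_id)
  if (nrow(edges) > 0) {
    if (!all(c(edges$from, edges$to) %in% genes$gene_id)) {
      stop("edge endpoint not in gene table")
    }
    if (any(sp[edges$from] == sp[edges$to])) {
      stop("edge joining two genes of the same species")
    }
  }
  if (is.null(clusters)) {
    n <- nrow(genes)
    clusters <- data.frame(gene_id = genes$gene_id,
                           cluster_id = sprintf("c%d", seq_len(n)),
                           flag = rep("ok", n),
                           left_anchor = rep(NA_character_, n),
                           right_anchor = rep(NA_character_, n),
                           stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, edges = edges, stage = stage,
                 clusters = clusters),
            class = "orthology_graph")
}

canonical_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  df <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.orthology_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat(sprintf("orthology graph (stage: %s)\n", x$stage))
  cat(sprintf("  %d genes in %d species, %d edges, %d components (%d clusters)\n",
              nrow(x$genes), length(unique(x$genes$species)),
              nrow(x$edges), length(unique(comp$component)),
              length(unique(x$clusters$cluster_id))))
  invisible(x)
}

# Flanking anchors of every gene within its own species (any anchor, no
# target filtering): the basis of the synteny cluster partition.
gene_flanks <- function(genes, anchors) {
  left <- right <- rep(NA_character_, nrow(genes))
  for (key in unique(paste(genes$species, genes$chrom))) {
    gi <- which(paste(genes$species, genes$chrom) == key)
    a <- anchors[paste(anchors$species, anchors$chrom) == key, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) == 0) next
    li <- findInterval(genes$start[gi], a$end)
    left[gi] <- ifelse(li >= 1, a$anchor_id[pmax(li, 1)], NA_character_)
    ri <- findInterval(genes$end[gi] - 0.5, a$start) + 1L
    right[gi] <- ifelse(ri <= nrow(a), a$anchor_id[pmin(ri, nrow(a))], NA_character_)
  }
  data.frame(gene_id = genes$gene_id, left_anchor = left, right_anchor = right,
             stringsAsFactors = FALSE)
}

#' Build the candidate graph from genes and anchors
#'
#' A cross-species edge is inserted when each gene lies between the tight
#' anchor pair of the other, i.e. both genes are mutually enclosed by the
#' nearest anchors shared between their species.  Genes whose tight anchor
#' pair is missing on a side, or resolves to different target chromosomes,
#' are kept as flagged singletons.  Genes sharing the same flanking anchor
#' pair form a synteny cluster (including same-species co-members).
#'
#' @param genes gene table.
#' @param anchors anchor placement table.
#' @param allow_inversions also accept genes whose placement between the
#'   anchors is order-reversed relative to the query (local inversions).
#' @return an `orthology_graph` at stage `"candidate"`.
#' @export
build_candidate_graph <- function(genes, anchors, allow_inversions = FALSE) {
  species <- unique(genes$species)
  # flanking anchors in the gene's own species; genes sharing a flank
  # interval share a cluster, and clusters are connected across species
  # through the candidate edges (anchors need not carry the same id in
  # every species pair, e.g. protein-pair anchors)
  fl <- gene_flanks(genes, anchors)
  flag <- ifelse(is.na(fl$left_anchor) | is.na(fl$right_anchor), "missing", "ok")

  edges_from <- character(0); edges_to <- character(0)
  # directed enclosure hits, then intersect to get the mutual condition
  hits <- new.env(parent = emptyenv())
  for (a in species) {
    ga <- genes[genes$species == a, , drop = FALSE]
    for (b in setdiff(species, a)) {
      gb <- genes[genes$species == b, , drop = FALSE]
      for (i in seq_len(nrow(ga))) {
        pr <- tight_anchor_pair(ga[i, ], b, anchors)
        if (pr$status != "ok") next
        tb_l <- anchors[anchors$anchor_id == pr$left & anchors$species == b, ][1, ]
        tb_r <- anchors[anchors$anchor_id == pr$right & anchors$species == b, ][1, ]
        lo <- tb_l$end; hi <- tb_r$start
        if (lo > hi) {
          if (!allow_inversions) next        # orientation-inconsistent pair
          tmp <- lo; lo <- tb_r$end; hi <- tb_l$start
          if (lo > hi) next
        }
        sel <- gb$chrom == pr$target_chrom & gb$start >= lo & gb$end <= hi
        for (tid in gb$gene_id[sel]) {
          assign(paste(ga$gene_id[i], tid), TRUE, envir = hits)
        }
      }
    }
  }
  keys <- ls(hits)
  if (length(keys) > 0) {
    parts <- strsplit(keys, " ", fixed = TRUE)
    u <- vapply(parts, `[`, "", 1); v <- vapply(parts, `[`, "", 2)
    fwd <- paste(u, v); rev <- paste(v, u)
    mutual <- fwd[fwd %in% rev & u < v]
    if (length(mutual) > 0) {
      mp <- strsplit(mutual, " ", fixed = TRUE)
      edges_from <- vapply(mp, `[`, "", 1)
      edges_to <- vapply(mp, `[`, "", 2)
    }
  }
  edges <- data.frame(from = edges_from, to = edges_to,
                      stringsAsFactors = FALSE)

  # synteny clusters: same-species genes between the same flank pair, glued
  # across species by the candidate edges
  ig <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(genes$gene_id)
  fkey <- paste(genes$species, fl$left_anchor, fl$right_anchor)
  glue <- list()
  for (k in unique(fkey[flag == "ok"])) {
    m <- genes$gene_id[fkey == k & flag == "ok"]
    if (length(m) > 1) {
      glue[[length(glue) + 1]] <- data.frame(from = m[-length(m)], to = m[-1],
                                             stringsAsFactors = FALSE)
    }
  }
  cl_edges <- rbind(edges, if (length(glue)) do.call(rbind, glue))
  if (!is.null(cl_edges) && nrow(cl_edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(cl_edges$from, cl_edges$to))
  }
  memb <- igraph::components(ig)$membership
  clusters <- data.frame(gene_id = genes$gene_id,
                         cluster_id = ifelse(flag == "ok",
                                             sprintf("cl%04d", unname(memb[genes$gene_id])),
                                             paste0("orphan:", genes$gene_id)),
                         flag = flag,
                         left_anchor = fl$left_anchor,
                         right_anchor = fl$right_anchor,
                         stringsAsFactors = FALSE)

  orthology_graph(genes, edges, stage = "candidate", clusters = clusters)
}

#' Normalized sequence distance
#'
#' Edit distance normalized by the mean sequence length (default), or Hamming
#' distance normalized by the common length when lengths agree.
#'
#' @param s1,s2 nucleotide strings.
#' @param metric `"edit"` or `"hamming"`.
#' @return a proportion in `[0, 1]` (can slightly exceed 1 for edit distance
#'   on very different lengths); `NA` if a sequence is missing.
#' @export
seq_distance <- function(s1, s2, metric = c("edit", "hamming")) {
  metric <- match.arg(metric)
  if (is.na(s1) || is.na(s2) || !nzchar(s1) || !nzchar(s2)) return(NA_real_)
  if (metric == "hamming") {
    if (nchar(s1) != nchar(s2)) {
      stop("Hamming distance undefined for unequal lengths; use metric = \"edit\"")
    }
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    return(sum(a != b) / length(a))
  }
  as.numeric(utils::adist(s1, s2)) / mean(c(nchar(s1), nchar(s2)))
}

#' Distance pruning parameters
#'
#' @param threshold_fraction retain an edge when the normalized distance is
#'   strictly below this fraction of the sequence length (default 0.10, an
#'   upper bound on sequence divergence within the phylogenetic range of
#'   interest).
#' @param metric `"edit"` (default; defined for unequal lengths) or
#'   `"hamming"`.
#' @export
distance_params <- function(threshold_fraction = 0.10,
                            metric = c("edit", "hamming")) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  list(threshold_fraction = threshold_fraction, metric = match.arg(metric))
}

#' Prune candidate edges by sequence distance
#'
#' Removes edges joining clearly distinct sequences.  Anticodon identity is
#' deliberately not required: a remolded gene differs only in its anticodon
#' and must stay connected to its relatives.
#'
#' @param g candidate `orthology_graph`.
#' @param params see [distance_params()].
#' @return an `orthology_graph` at stage `"pruned"` (a spanning subgraph of
#'   the input).
#' @export
prune_by_distance <- function(g, params = distance_params()) {
  seqs <- stats::setNames(g$genes$sequence, g$genes$gene_id)
  keep <- logical(nrow(g$edges))
  for (i in seq_len(nrow(g$edges))) {
    d <- seq_distance(seqs[[g$edges$from[i]]], seqs[[g$edges$to[i]]],
                      params$metric)
    if (is.na(d)) {
      warning(sprintf("missing sequence for edge %s-%s; edge dropped",
                      g$edges$from[i], g$edges$to[i]))
      keep[i] <- FALSE
    } else {
      keep[i] <- d < params$threshold_fraction
    }
  }
  orthology_graph(g$genes, g$edges[keep, , drop = FALSE], "pruned", g$clusters)
}

#' Join synteny clusters sharing a boundary anchor
#'
#' Clusters delimited by a common anchor are merged into one (transitively);
#' the edge set is untouched, so the number of connected components can only
#' stay or decrease.
#'
#' @param g an `orthology_graph` whose clusters carry boundary anchor ids.
#' @return the graph with a coarser cluster partition.
#' @export
join_components <- function(g) {
  cl <- g$clusters
  ids <- unique(cl$cluster_id)
  bounds <- lapply(ids, function(cid) {
    r <- cl[cl$cluster_id == cid, ]
    stats::na.omit(unique(c(r$left_anchor, r$right_anchor)))
  })
  # union-find over clusters via shared boundary anchors
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  anchor_owner <- list()
  for (i in seq_along(ids)) {
    for (a in bounds[[i]]) {
      if (!is.null(anchor_owner[[a]])) {
        ri <- find(i); rj <- find(anchor_owner[[a]])
        if (ri != rj) parent[ri] <- rj
      } else anchor_owner[[a]] <- i
    }
  }
  root <- vapply(seq_along(ids), find, 1L)
  merged <- stats::setNames(paste0("j", root), ids)
  cl$cluster_id <- unname(merged[cl$cluster_id])
  orthology_graph(g$genes, g$edges, g$stage, cl)
}

#' Compare two orthology graphs by their edge sets
#'
#' @param g1,g2 `orthology_graph` objects (or plain edge `data.frame`s) over
#'   comparable gene ids.
#' @return list with `shared`, `only_g1`, `only_g2` edge tables and
#'   `symmetric_difference` count.
#' @export
graph_compare <- function(g1, g2) {
  e1 <- canonical_edges(if (inherits(g1, "orthology_graph")) g1$edges else g1)
  e2 <- canonical_edges(if (inherits(g2, "orthology_graph")) g2$edges else g2)
  k1 <- paste(e1$from, e1$to); k2 <- paste(e2$from, e2$to)
  list(
    shared = e1[k1 %in% k2, , drop = FALSE],
    only_g1 = e1[!(k1 %in% k2), , drop = FALSE],
    only_g2 = e2[!(k2 %in% k1), , drop = FALSE],
    symmetric_difference = sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
  )
}

#' Connected components of an orthology graph
#'
#' @param g an `orthology_graph`.
#' @param use_clusters also connect genes that share a synteny cluster, so
#'   that edgeless single-species clusters form components (default `TRUE`).
#' @return `data.frame` with columns `gene_id`, `component`.
#' @export
graph_components <- function(g, use_clusters = TRUE) {
  if (nrow(g$genes) == 0) {
    return(data.frame(gene_id = character(0), component = integer(0),
                      stringsAsFactors = FALSE))
  }
  ig <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(g$genes$gene_id)
  el <- g$edges
  if (use_clusters) {
    # chain up genes of each cluster (membership only; these are not edges
    # of the orthology relation)
    cl <- g$clusters[g$clusters$gene_id %in% g$genes$gene_id, ]
    for (cid in unique(cl$cluster_id)) {
      m <- cl$gene_id[cl$cluster_id == cid]
      if (length(m) > 1) {
        el <- rbind(el, data.frame(from = m[-length(m)], to = m[-1],
                                   stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(el) > 0) {
    ig <- igraph::add_edges(ig, rbind(el$from, el$to))
  }
  memb <- igraph::components(ig)$membership
  data.frame(gene_id = names(memb), component = unname(memb),
             stringsAsFactors = FALSE)
}

# Edge-only connected components as a list of gene-id vectors.
edge_components <- function(g) {
  comp <- graph_components(g, use_clusters = FALSE)
  split(comp$gene_id, comp$component)
}
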