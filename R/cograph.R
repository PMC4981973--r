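# Cograph machinery: P4 detection, minimum edge editing, cotree
# construction and duplication read-off.  Valid orthology relations are
# P4-free, so each connected component of the estimated graph is corrected
# to its nearest cograph and converted to a cotree whose parallel (= series
# complement) nodes mark duplication events.

.adj_matrix <- function(vertices, edges) {
  n <- length(vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  if (!is.null(edges) && nrow(edges) > 0) {
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj[cbind(edges$to, edges$from)] <- TRUE
  }
  adj
}

.adj_edges <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  v <- rownames(adj)
  canonical_edges(data.frame(from = v[idx[, 1]], to = v[idx[, 2]],
                             stringsAsFactors = FALSE))
}

# Induced-P4 test on a 4x4 adjacency submatrix; returns the path order
# (indices into the subset) or NULL.
.p4_order <- function(sub) {
  deg <- rowSums(sub)
  if (sum(sub) != 6 || max(deg) != 2 || min(deg) != 1) return(NULL)
  ends <- which(deg == 1)
  a <- ends[1]
  b <- which(sub[a, ])[1]
  c <- setdiff(which(sub[b, ]), a)[1]
  d <- setdiff(which(sub[c, ]), b)[1]
  if (!sub[c, d] || sub[a, d] || sub[a, c] || sub[b, d]) return(NULL)
  c(a, b, c, d)
}

#' Find all induced paths on four vertices
#'
#' A graph is a cograph exactly when it has no induced P4; this exhaustively
#' lists them over all 4-vertex subsets.
#'
#' @param vertices character vector of vertex ids.
#' @param edges edge `data.frame` (`from`, `to`).
#' @return list of length-4 character vectors in path order (first endpoint
#'   smaller than the last); empty list for cographs.
#' @export
find_p4 <- function(vertices, edges) {
  n <- length(vertices)
  if (n < 4) return(list())
  adj <- .adj_matrix(vertices, edges)
  out <- list()
  subsets <- utils::combn(n, 4)
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    ord <- .p4_order(adj[s, s])
    if (!is.null(ord)) {
      path <- vertices[s[ord]]
      if (path[1] > path[4]) path <- rev(path)
      out[[length(out) + 1]] <- path
    }
  }
  out
}

# First P4 found, as vertex indices, or NULL.  Used in the editing search.
.first_p4 <- function(adj) {
  n <- nrow(adj)
  if (n < 4) return(NULL)
  subsets <- utils::combn(n, 4)
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    ord <- .p4_order(adj[s, s])
    if (!is.null(ord)) return(s[ord])
  }
  NULL
}

.count_p4 <- function(adj) {
  n <- nrow(adj)
  if (n < 4) return(0L)
  subsets <- utils::combn(n, 4)
  sum(vapply(seq_len(ncol(subsets)), function(k) {
    s <- subsets[, k]
    !is.null(.p4_order(adj[s, s]))
  }, logical(1)))
}

#' Is the graph a cograph (P4-free)?
#' @inheritParams find_p4
#' @export
is_cograph <- function(vertices, edges) {
  is.null(.first_p4(.adj_matrix(vertices, edges)))
}

# Exhaustive branch-and-bound: all edit sets of size exactly k that make adj
# P4-free.  Branches over the 6 vertex pairs of a found P4 (any valid edit
# set must touch every induced P4); `locked` prevents re-editing a pair on
# the current path, preserving completeness.  `species` (named vector) bans
# insertions between same-species vertices.
.edit_search <- function(adj, k, locked, edits, species, acc) {
  p4 <- .first_p4(adj)
  if (is.null(p4)) {
    key <- paste(sort(unlist(edits)), collapse = ";")
    acc[[key]] <- edits
    return(acc)
  }
  if (k == 0) return(acc)
  pairs <- utils::combn(p4, 2)
  for (c_i in seq_len(ncol(pairs))) {
    u <- min(pairs[, c_i]); v <- max(pairs[, c_i])
    pk <- paste(u, v)
    if (pk %in% locked) next
    inserting <- !adj[u, v]
    if (inserting && !is.null(species) &&
        species[rownames(adj)[u]] == species[rownames(adj)[v]]) next
    adj[u, v] <- adj[v, u] <- !adj[u, v]
    op <- if (inserting) "add" else "del"
    acc <- .edit_search(adj, k - 1L, c(locked, pk),
                        c(edits, paste(op, rownames(adj)[u], rownames(adj)[v])),
                        species, acc)
    adj[u, v] <- adj[v, u] <- !adj[u, v]
  }
  acc
}

.edits_to_df <- function(edits) {
  if (length(edits) == 0) {
    return(data.frame(op = character(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(edits, " ", fixed = TRUE)
  df <- data.frame(op = vapply(parts, `[`, "", 1),
                   from = vapply(parts, `[`, "", 2),
                   to = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  a <- pmin(df$from, df$to); b <- pmax(df$from, df$to)
  df$from <- a; df$to <- b
  df[order(df$op, df$from, df$to), , drop = FALSE]
}

#' Edit a connected component to its nearest cograph
#'
#' Finds a minimum-cardinality set of edge insertions and deletions that
#' destroys every induced P4.  Components up to `exact_bound` vertices are
#' solved exactly by exhaustive branch-and-bound over P4s; among multiple
#' optima the set with the most insertions is preferred (missing edges
#' typically stem from pseudogenized pairs just past the distance
#' threshold), then lexicographic order.  Larger components up to
#' `hard_cap` use a greedy P4-destruction heuristic and are flagged
#' non-optimal; components above `hard_cap` are returned unedited with a
#' diagnostic flag.
#'
#' @param vertices,edges the component.
#' @param species optional named vector (gene id -> species); when given,
#'   insertions between same-species genes are forbidden, preserving the
#'   multipartite structure of an orthology relation.
#' @param exact_bound largest component size for exact search (default 10).
#' @param hard_cap largest size attempted at all (default 40).
#' @return list with `edits` (`data.frame`: `op`, `from`, `to`), `size`,
#'   `optimal` (logical), `edited` (logical) and `edges`, the edited edge
#'   set.
#' @export
edit_to_cograph <- function(vertices, edges, species = NULL,
                            exact_bound = 10, hard_cap = 40) {
  adj <- .adj_matrix(vertices, edges)
  if (is.null(.first_p4(adj))) {
    return(list(edits = .edits_to_df(character(0)), size = 0L,
                optimal = TRUE, edited = TRUE, edges = canonical_edges(edges)))
  }
  n <- length(vertices)
  if (n > hard_cap) {
    warning(sprintf("component with %d vertices exceeds hard cap %d; left unedited",
                    n, hard_cap))
    return(list(edits = .edits_to_df(character(0)), size = NA_integer_,
                optimal = FALSE, edited = FALSE,
                edges = canonical_edges(edges)))
  }
  if (n <= exact_bound) {
    for (k in 1:(n * (n - 1) / 2)) {
      acc <- .edit_search(adj, k, character(0), character(0), species, list())
      if (length(acc) > 0) {
        sols <- lapply(acc, identity)
        n_ins <- vapply(sols, function(s) sum(startsWith(s, "add")), 0L)
        keys <- vapply(sols, function(s) paste(sort(s), collapse = ";"), "")
        ord <- order(-n_ins, keys)
        best <- sols[[ord[1]]]
        df <- .edits_to_df(best)
        return(list(edits = df, size = length(best), optimal = TRUE,
                    edited = TRUE,
                    edges = apply_edits(vertices, edges, df)))
      }
    }
    stop("exact cograph editing failed unexpectedly")  # unreachable
  }
  # greedy fallback: repeatedly apply the toggle that minimizes the number
  # of remaining P4s; ties prefer insertions, then lexicographic pairs
  edits <- character(0)
  for (iter in 1:200) {
    p4 <- .first_p4(adj)
    if (is.null(p4)) break
    pairs <- utils::combn(p4, 2)
    best_cnt <- Inf; best <- NULL
    for (c_i in seq_len(ncol(pairs))) {
      u <- min(pairs[, c_i]); v <- max(pairs[, c_i])
      inserting <- !adj[u, v]
      if (inserting && !is.null(species) &&
          species[rownames(adj)[u]] == species[rownames(adj)[v]]) next
      adj[u, v] <- adj[v, u] <- !adj[u, v]
      cnt <- .count_p4(adj)
      adj[u, v] <- adj[v, u] <- !adj[u, v]
      cand <- list(u = u, v = v, inserting = inserting, cnt = cnt)
      better <- cnt < best_cnt ||
        (cnt == best_cnt && !is.null(best) && inserting && !best$inserting) ||
        (cnt == best_cnt && !is.null(best) && inserting == best$inserting &&
           paste(rownames(adj)[u], rownames(adj)[v]) <
             paste(rownames(adj)[best$u], rownames(adj)[best$v]))
      if (is.null(best) || better) { best_cnt <- cnt; best <- cand }
    }
    if (is.null(best)) break
    adj[best$u, best$v] <- adj[best$v, best$u] <- !adj[best$u, best$v]
    op <- if (best$inserting) "add" else "del"
    edits <- c(edits, paste(op, rownames(adj)[best$u], rownames(adj)[best$v]))
  }
  # safety net: deletion of a P4's middle edge strictly reduces the edge
  # count, so this always terminates in an (edgeless at worst) cograph
  repeat {
    p4 <- .first_p4(adj)
    if (is.null(p4)) break
    u <- min(p4[2], p4[3]); v <- max(p4[2], p4[3])
    adj[u, v] <- adj[v, u] <- FALSE
    edits <- c(edits, paste("del", rownames(adj)[u], rownames(adj)[v]))
  }
  df <- .edits_to_df(edits)
  list(edits = df, size = length(edits), optimal = FALSE, edited = TRUE,
       edges = apply_edits(vertices, edges, df))
}

#' Apply an edit set to an edge list
#' @param vertices vertex ids.
#' @param edges edge `data.frame`.
#' @param edits edit `data.frame` (`op`, `from`, `to`).
#' @return the edited canonical edge `data.frame`.
#' @export
apply_edits <- function(vertices, edges, edits) {
  adj <- .adj_matrix(vertices, edges)
  for (i in seq_len(nrow(edits))) {
    val <- edits$op[i] == "add"
    adj[edits$from[i], edits$to[i]] <- val
    adj[edits$to[i], edits$from[i]] <- val
  }
  .adj_edges(adj)
}

#' Cotree of a cograph
#'
#' Recursive modular decomposition: a disconnected (sub)graph roots a
#' parallel node over its components, a connected one roots a series node
#' over the components of its complement.  Series nodes correspond to
#' speciations, parallel nodes to duplications.  Children are ordered by
#' their smallest leaf id, making the result canonical.
#'
#' @param vertices,edges the component (must be P4-free).
#' @return a nested-list cotree: leaves are `list(label = "leaf", gene = id)`,
#'   internal nodes `list(label = "S"|"D", children = ...)` with no two
#'   adjacent internal nodes sharing a label.
#' @export
cograph_to_cotree <- function(vertices, edges) {
  adj <- .adj_matrix(vertices, edges)
  if (!is.null(.first_p4(adj))) {
    stop("graph contains an induced P4; run edit_to_cograph() first")
  }
  build <- function(vs) {
    if (length(vs) == 1) return(list(label = "leaf", gene = vs))
    sub <- adj[vs, vs, drop = FALSE]
    ig <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    memb <- igraph::components(ig)$membership
    if (max(memb) > 1) {
      kids <- lapply(split(vs, memb), build)
      node <- list(label = "D", children = unname(kids))
    } else {
      co <- !sub; diag(co) <- FALSE
      igc <- igraph::graph_from_adjacency_matrix(co, mode = "undirected")
      membc <- igraph::components(igc)$membership
      if (max(membc) == 1) stop("connected with connected complement: not a cograph")
      kids <- lapply(split(vs, membc), build)
      node <- list(label = "S", children = unname(kids))
    }
    key <- vapply(node$children, function(k) min(cotree_leaves(k)), "")
    node$children <- node$children[order(key)]
    node
  }
  build(sort(vertices))
}

#' Leaves of a cotree
#' @param tree a cotree.
#' @return character vector of leaf gene ids.
#' @export
cotree_leaves <- function(tree) {
  if (tree$label == "leaf") return(tree$gene)
  unlist(lapply(tree$children, cotree_leaves))
}

#' Reconstruct the cograph of a cotree
#'
#' Two leaves are adjacent exactly when their lowest common ancestor is a
#' series node.  Inverse of [cograph_to_cotree()] on canonical cotrees.
#'
#' @param tree a cotree.
#' @return canonical edge `data.frame`.
#' @export
cotree_to_cograph <- function(tree) {
  edges <- list()
  walk <- function(node) {
    if (node$label == "leaf") return(invisible())
    if (node$label == "S") {
      lv <- lapply(node$children, cotree_leaves)
      for (i in seq_len(length(lv) - 1)) {
        for (j in (i + 1):length(lv)) {
          edges[[length(edges) + 1]] <<-
            expand.grid(from = lv[[i]], to = lv[[j]], stringsAsFactors = FALSE)
        }
      }
    }
    for (k in node$children) walk(k)
  }
  walk(tree)
  canonical_edges(if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Count duplication events in a cotree
#'
#' Each parallel node with c children stands for c-1 duplication events; a
#' clique component (single series node) therefore contains none.  A series
#' node whose descendants include two genes of the same species would
#' contradict orthology and raises an error.
#'
#' @param tree a cotree.
#' @param species_of named character vector, gene id -> species.
#' @return integer duplication count.
#' @export
count_duplications <- function(tree, species_of) {
  total <- 0L
  walk <- function(node) {
    if (node$label == "leaf") return(invisible())
    if (node$label == "S") {
      lv <- lapply(node$children, function(k) unique(species_of[cotree_leaves(k)]))
      for (i in seq_len(length(lv) - 1)) {
        for (j in (i + 1):length(lv)) {
          if (length(intersect(lv[[i]], lv[[j]])) > 0) {
            stop("series node over same-species genes: orthology violation")
          }
        }
      }
    } else {
      total <<- total + length(node$children) - 1L
    }
    for (k in node$children) walk(k)
  }
  walk(tree)
  total
}

#' Newick export of a cotree
#'
#' Internal nodes are labelled `S` (speciation/series) or `D`
#' (duplication/parallel).
#'
#' @param tree a cotree.
#' @return a Newick string (with trailing semicolon).
#' @export
cotree_newick <- function(tree) {
  fmt <- function(node) {
    if (node$label == "leaf") return(node$gene)
    paste0("(", paste(vapply(node$children, fmt, ""), collapse = ","), ")",
           node$label)
  }
  paste0(fmt(tree), ";")
}

#' Edit every component of an orthology graph to a cograph
#'
#' Edge-connected components are edited independently; insertions between
#' same-species genes are forbidden throughout so the result stays a valid
#' multipartite orthology relation.
#'
#' @param g an `orthology_graph` (typically stage `"estimated"`).
#' @param exact_bound,hard_cap see [edit_to_cograph()].
#' @return list with `graph` (stage `"edited"`) and `edit_log`, a
#'   `data.frame` of applied edits (`component`, `op`, `from`, `to`,
#'   `optimal`).
#' @export
edit_orthology_graph <- function(g, exact_bound = 10, hard_cap = 40) {
  species_of <- stats::setNames(g$genes$species, g$genes$gene_id)
  comps <- edge_components(g)
  logs <- list(); new_edges <- list()
  for (i in seq_along(comps)) {
    ids <- comps[[i]]
    sub <- g$edges[g$edges$from %in% ids & g$edges$to %in% ids, , drop = FALSE]
    if (length(ids) < 4) { new_edges[[i]] <- sub; next }
    res <- edit_to_cograph(ids, sub, species = species_of,
                           exact_bound = exact_bound, hard_cap = hard_cap)
    new_edges[[i]] <- res$edges
    if (nrow(res$edits) > 0) {
      logs[[length(logs) + 1]] <- cbind(component = i, res$edits,
                                        optimal = res$optimal)
    }
  }
  E <- canonical_edges(do.call(rbind, new_edges))
  list(graph = orthology_graph(g$genes, E, "edited", g$clusters),
       edit_log = if (length(logs)) do.call(rbind, logs) else
         data.frame(component = integer(0), op = character(0),
                    from = character(0), to = character(0),
                    optimal = logical(0)))
}
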