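# Anticodon remolding: a point mutation in the anticodon changes which codon
# a tRNA reads.  Isoacceptor remolding keeps the amino acid; alloacceptor
# remolding changes it.  Events are detected per co-ortholog group by
# parsimony over anticodon states on the group's gene tree.

# standard genetic code, DNA codons -> three-letter amino acid names
.GENETIC_CODE3 <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "Stop", TAG = "Stop",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "Stop", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
)

.revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, "")
}

.check_anticodon <- function(ac) {
  ac <- toupper(ac)
  if (any(nchar(ac) != 3) || any(grepl("[^ACGT]", ac))) {
    stop("anticodon must be a 3-mer over A, C, G, T")
  }
  ac
}

#' Amino acid decoded by an anticodon
#'
#' The anticodon is reverse-complemented to the codon it reads and looked up
#' in the standard genetic code.
#'
#' @param ac anticodon 3-mer(s), DNA alphabet.
#' @return three-letter amino acid name(s) (`"Stop"` for anticodons reading
#'   stop codons).
#' @export
anticodon_to_aa <- function(ac) {
  ac <- .check_anticodon(ac)
  unname(.GENETIC_CODE3[.revcomp(ac)])
}

#' Classify an anticodon change
#'
#' @param ac_from,ac_to source and target anticodons.
#' @return `"none"` if identical, `"iso"` if both decode the same amino acid
#'   (isoacceptor remolding), `"allo"` otherwise.
#' @export
classify_remolding <- function(ac_from, ac_to) {
  ac_from <- .check_anticodon(ac_from)
  ac_to <- .check_anticodon(ac_to)
  ifelse(ac_from == ac_to, "none",
         ifelse(anticodon_to_aa(ac_from) == anticodon_to_aa(ac_to),
                "iso", "allo"))
}

# --- parsimony over anticodon states on a component's gene tree ------------

# Fitch-style small parsimony on a cotree with anticodon leaf states.
# Returns events: data.frame(from, to, node_leaves (collapsed), ambiguous).
.anticodon_parsimony <- function(tree, anticodon_of) {
  # bottom-up state sets
  annotate <- function(node) {
    if (node$label == "leaf") {
      node$set <- unname(anticodon_of[node$gene])
      return(node)
    }
    node$children <- lapply(node$children, annotate)
    sets <- lapply(node$children, `[[`, "set")
    inter <- Reduce(intersect, sets)
    node$set <- if (length(inter) > 0) inter else sort(unique(unlist(sets)))
    node
  }
  # leaf-count majority; ties broken lexicographically (flagged)
  counts <- table(anticodon_of)
  pick <- function(set) {
    set <- sort(set)
    cnt <- counts[set]; cnt[is.na(cnt)] <- 0
    best <- set[cnt == max(cnt)]
    list(state = best[1], ambiguous = length(best) > 1)
  }
  events <- list()
  assign_down <- function(node, parent_state) {
    if (!is.null(parent_state) && parent_state %in% node$set) {
      state <- parent_state; amb <- FALSE
    } else {
      p <- pick(node$set); state <- p$state; amb <- p$ambiguous
    }
    if (!is.null(parent_state) && state != parent_state) {
      events[[length(events) + 1]] <<- data.frame(
        from = parent_state, to = state,
        leaves = paste(sort(cotree_leaves(node)), collapse = ","),
        ambiguous = amb, stringsAsFactors = FALSE)
    }
    if (node$label != "leaf") {
      for (k in node$children) assign_down(k, state)
    }
  }
  tr <- annotate(tree)
  if (tr$label == "leaf") return(NULL)
  assign_down(tr, NULL)
  if (length(events) == 0) return(NULL)
  do.call(rbind, events)
}

#' Detect anticodon remolding events
#'
#' Within each synteny component, genes are first grouped by sequence
#' similarity (paralogs under concerted evolution stay near-identical even
#' across ortholog groups, which is what allows a duplication-then-remolding
#' history to be seen as one unit).  Groups whose members carry at least two
#' distinct anticodons are analysed: the group's gene tree (cotrees of its
#' ortholog subcomponents, joined under a duplication root when there are
#' several) is labelled by parsimony over anticodon states, and every state
#' change becomes one remolding event on the species-tree branch above the
#' last common ancestor of the species below the change (the terminal branch
#' for single-species changes).  Parsimony ties are broken toward the
#' lexicographically smaller state and flagged ambiguous.
#'
#' @param g an `orthology_graph` (typically stage `"edited"`).
#' @param tree species tree (`ape::phylo`, rooted).
#' @param threshold_fraction similarity threshold for grouping (default
#'   0.10, as in distance pruning).
#' @return `data.frame` with columns `component`, `branch`, `from`, `to`,
#'   `class`, `ambiguous`; zero rows when no events are found.
#' @export
detect_remoldings <- function(g, tree, threshold_fraction = 0.10) {
  comp <- graph_components(g, use_clusters = TRUE)
  genes <- g$genes
  anticodon_of <- stats::setNames(genes$anticodon, genes$gene_id)
  seq_of <- stats::setNames(genes$sequence, genes$gene_id)
  species_of <- stats::setNames(genes$species, genes$gene_id)
  out <- list()
  for (cid in unique(comp$component)) {
    ids <- comp$gene_id[comp$component == cid]
    ids <- ids[!is.na(anticodon_of[ids])]
    if (length(ids) < 2) next
    # similarity groups within the component
    groups <- .similarity_groups(ids, seq_of, threshold_fraction)
    for (grp in groups) {
      acs <- unique(anticodon_of[grp])
      if (length(grp) < 2 || length(acs) < 2) next
      gtree <- .group_gene_tree(g, grp)
      ev <- .anticodon_parsimony(gtree, anticodon_of[grp])
      if (is.null(ev)) next
      for (i in seq_len(nrow(ev))) {
        lv <- strsplit(ev$leaves[i], ",", fixed = TRUE)[[1]]
        spp <- unique(species_of[lv])
        branch <- if (length(spp) == 1) spp else {
          node_key(tree, ape::getMRCA(tree, spp))
        }
        out[[length(out) + 1]] <- data.frame(
          component = cid, branch = branch,
          from = ev$from[i], to = ev$to[i],
          class = classify_remolding(ev$from[i], ev$to[i]),
          ambiguous = ev$ambiguous[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(component = integer(0), branch = character(0),
                      from = character(0), to = character(0),
                      class = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[res$class != "none", , drop = FALSE]
}

# union-find over sequence similarity
.similarity_groups <- function(ids, seq_of, threshold) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1 && !all(is.na(seq_of[ids]))) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- seq_distance(seq_of[[ids[i]]], seq_of[[ids[j]]])
        if (!is.na(d) && d < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(ids, roots))
}

# gene tree of a similarity group: cotrees of its ortholog subcomponents,
# joined under a duplication root when the group spans several
.group_gene_tree <- function(g, grp) {
  sub_edges <- g$edges[g$edges$from %in% grp & g$edges$to %in% grp, , drop = FALSE]
  ig <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(grp)
  if (nrow(sub_edges) > 0) ig <- igraph::add_edges(ig, rbind(sub_edges$from, sub_edges$to))
  memb <- igraph::components(ig)$membership
  parts <- split(names(memb), memb)
  trees <- lapply(parts, function(vs) {
    cograph_to_cotree(vs, sub_edges[sub_edges$from %in% vs & sub_edges$to %in% vs, , drop = FALSE])
  })
  if (length(trees) == 1) return(trees[[1]])
  node <- list(label = "D", children = unname(trees))
  key <- vapply(node$children, function(k) min(cotree_leaves(k)), "")
  node$children <- node$children[order(key)]
  node
}
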