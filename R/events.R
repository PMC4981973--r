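# Dollo-parsimony mapping of co-ortholog groups onto the species tree:
# a locus is gained once (on the branch above the last common ancestor of
# the species that carry it) and lost arbitrarily often.

#' Stable key of a species-tree branch
#'
#' Branches are addressed by their child node: the species name for terminal
#' branches, the sorted `+`-joined tip set for internal nodes (the root key
#' names the whole tip set).
#'
#' @param tree `ape::phylo`, rooted.
#' @param node node number.
#' @return character key.
#' @export
node_key <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "+")
}

#' All branch keys of a tree (including the root)
#' @param tree `ape::phylo`, rooted.
#' @return character vector, tips first, then internal nodes.
#' @export
all_branch_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  vapply(seq_len(ntip + tree$Nnode), function(n) node_key(tree, n), "")
}

.children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Dollo gains and losses for one co-ortholog group
#'
#' By default the locus is gained once on the branch above the last common
#' ancestor of the observed species, and lost on the minimal set of branches
#' pruning all absent descendants.  A configurable exception reproduces the
#' practice of assigning two independent lineage-specific gains to groups
#' consisting of exactly one outgroup-adjacent and one deep-ingroup species
#' (where a single deep gain would otherwise imply many parallel losses).
#'
#' @param leafset character vector of species carrying the locus.
#' @param tree `ape::phylo`, rooted; all dataset species must be tips.
#' @param exception_pairs list of length-2 character vectors; a leafset
#'   equal to such a pair yields two terminal gains and no losses.
#' @return list with `gains` and `losses`, both vectors of branch keys.
#' @export
dollo_events <- function(leafset, tree, exception_pairs = list()) {
  leafset <- unique(leafset)
  if (length(leafset) == 0) stop("empty leafset")
  missing <- setdiff(leafset, tree$tip.label)
  if (length(missing) > 0) {
    stop(sprintf("species not in tree: %s", paste(missing, collapse = ", ")))
  }
  for (p in exception_pairs) {
    if (length(leafset) == 2 && setequal(leafset, p)) {
      return(list(gains = sort(leafset), losses = character(0)))
    }
  }
  if (length(leafset) == 1) {
    return(list(gains = leafset, losses = character(0)))
  }
  mrca <- ape::getMRCA(tree, leafset)
  losses <- character(0)
  walk <- function(node) {
    for (ch in .children(tree, node)) {
      tips <- .clade_tips(tree, ch)
      if (any(tips %in% leafset)) walk(ch)
      else losses <<- c(losses, node_key(tree, ch))
    }
  }
  walk(mrca)
  list(gains = node_key(tree, mrca), losses = losses)
}

#' Per-branch event table from an edited orthology graph
#'
#' Each edge-connected component of the graph is one co-ortholog group: its
#' species set is mapped by Dollo parsimony (gain above the LCA, minimal
#' losses), and the duplications read off its cotree are assigned to the
#' gain branch.  Genes without any orthology edge are grouped per synteny
#' cluster and species, subdivided into families by sequence similarity;
#' each family contributes one terminal gain plus one duplication per
#' additional copy.  Pseudogene-flagged genes are tallied on their species'
#' terminal branch.
#'
#' @param g an `orthology_graph` whose edge components are cographs (stage
#'   `"edited"`, or any graph known to be P4-free; also used on the
#'   simulator's true orthology relation).
#' @param tree species tree (`ape::phylo`, rooted).
#' @param exception_pairs see [dollo_events()].
#' @param threshold_fraction similarity threshold for the single-species
#'   family grouping.
#' @return list with `table` (`data.frame`: `branch`, `gains_seeding`,
#'   `duplications`, `losses`, `total_gain`, `pseudogenes`) and `components`
#'   (per-group detail: species, gain branch, losses, duplications).
#' @export
summarize_events <- function(g, tree, exception_pairs = list(),
                             threshold_fraction = 0.10) {
  keys <- all_branch_keys(tree)
  tab <- data.frame(branch = keys,
                    gains_seeding = 0, duplications = 0, losses = 0,
                    stringsAsFactors = FALSE)
  rownames(tab) <- keys
  species_of <- stats::setNames(g$genes$species, g$genes$gene_id)
  seq_of <- stats::setNames(g$genes$sequence, g$genes$gene_id)
  absent <- setdiff(unique(g$genes$species), tree$tip.label)
  if (length(absent) > 0) {
    stop(sprintf("species not in tree: %s", paste(absent, collapse = ", ")))
  }
  detail <- list()

  comps <- edge_components(g)
  multi <- comps[vapply(comps, length, 1L) > 1]
  single <- unlist(comps[vapply(comps, length, 1L) == 1], use.names = FALSE)

  for (ids in multi) {
    spp <- unique(species_of[ids])
    ev <- dollo_events(spp, tree, exception_pairs)
    sub <- g$edges[g$edges$from %in% ids & g$edges$to %in% ids, , drop = FALSE]
    ct <- cograph_to_cotree(ids, sub)
    nd <- count_duplications(ct, species_of)
    tab[ev$gains, "gains_seeding"] <- tab[ev$gains, "gains_seeding"] + 1
    for (l in ev$losses) tab[l, "losses"] <- tab[l, "losses"] + 1
    tab[ev$gains[1], "duplications"] <- tab[ev$gains[1], "duplications"] + nd
    detail[[length(detail) + 1]] <- data.frame(
      genes = paste(sort(ids), collapse = ","),
      species = paste(sort(spp), collapse = ","),
      gain = paste(ev$gains, collapse = ","),
      n_losses = length(ev$losses), duplications = nd,
      stringsAsFactors = FALSE)
  }

  # edge-singletons: cluster- and species-wise family grouping
  if (length(single) > 0) {
    cl <- g$clusters
    ckey <- stats::setNames(cl$cluster_id, cl$gene_id)
    grp_key <- paste(ckey[single], species_of[single])
    for (k in unique(grp_key)) {
      ids <- single[grp_key == k]
      fams <- .similarity_groups(ids, seq_of, threshold_fraction)
      sp <- species_of[ids[1]]
      for (f in fams) {
        tab[sp, "gains_seeding"] <- tab[sp, "gains_seeding"] + 1
        tab[sp, "duplications"] <- tab[sp, "duplications"] + length(f) - 1
        detail[[length(detail) + 1]] <- data.frame(
          genes = paste(sort(f), collapse = ","), species = sp,
          gain = sp, n_losses = 0, duplications = length(f) - 1,
          stringsAsFactors = FALSE)
      }
    }
  }

  tab$total_gain <- tab$gains_seeding + tab$duplications
  ps <- table(g$genes$species[g$genes$pseudogene])
  tab$pseudogenes <- 0
  tab[names(ps), "pseudogenes"] <- as.numeric(ps)
  rownames(tab) <- NULL
  list(table = tab,
       components = if (length(detail)) do.call(rbind, detail) else NULL)
}

#' Intron presence consistency of co-ortholog groups
#'
#' Orthologous tRNAs are expected to agree on intron presence; a group in
#' which some members carry an intron and others do not is flagged as a
#' putative misassignment.  For consistent intron-bearing groups the range
#' of intron lengths is reported.
#'
#' @param g an `orthology_graph`.
#' @return `data.frame` with one row per multi-gene edge component:
#'   `n_with`, `n_without`, `consistent`, `min_intron_len`,
#'   `max_intron_len`.
#' @export
intron_consistency <- function(g) {
  comps <- edge_components(g)
  comps <- comps[vapply(comps, length, 1L) > 1]
  introns <- stats::setNames(g$genes$introns, g$genes$gene_id)
  rows <- lapply(seq_along(comps), function(i) {
    ids <- comps[[i]]
    has <- vapply(introns[ids], function(x) !is.null(x) && NROW(x) > 0, TRUE)
    lens <- unlist(lapply(introns[ids][has], function(m) m[, 2] - m[, 1]))
    data.frame(component = i,
               genes = paste(sort(ids), collapse = ","),
               n_with = sum(has), n_without = sum(!has),
               consistent = sum(has) == 0 || sum(!has) == 0,
               min_intron_len = if (length(lens)) min(lens) else NA_real_,
               max_intron_len = if (length(lens)) max(lens) else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(component = integer(0), genes = character(0),
                      n_with = integer(0), n_without = integer(0),
                      consistent = logical(0), min_intron_len = numeric(0),
                      max_intron_len = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
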