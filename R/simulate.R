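# Forward simulation of tRNA cluster evolution along a species tree, with
# full ground truth (gene genealogy, true orthology relation, event log).
# Concerted evolution is modelled phenomenologically: gene copies are
# resampled from a per-species family consensus with small noise, so
# paralogs stay near-identical within a species while families drift apart
# between species -- exactly the property that defeats sequence-based
# orthology and motivates the synteny approach.

#' Default six-species tree for simulations
#'
#' A primate-like ladder topology with branch lengths in arbitrary
#' evolutionary time units (root-to-tip depth 0.8).
#'
#' @return an `ape::phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((Hsa:0.1,Ptr:0.1):0.1,Ggo:0.2):0.2,Pab:0.4):0.2,Nle:0.6):0.2,",
    "Mmu:0.8);"))
}

#' Simulation configuration
#'
#' Per-gene rates are events per gene per unit branch length; the seeding
#' rate is per genome per unit branch length.  Defaults describe a slowly
#' turning-over cluster system: a handful of duplication, loss, seeding and
#' remolding events across the whole tree, sequence drift well inside the
#' 10 % orthology threshold, and intact anchors.
#'
#' @param tree species tree with branch lengths (`ape::phylo`).
#' @param rate_dup,rate_loss,rate_remold,rate_pseudo per-gene event rates.
#' @param rate_seed genome-wide rate of seeding a new locus.
#' @param rate_anchor_loss genome-wide rate of losing an anchor placement.
#' @param subst_rate per-site substitution rate of the family consensus.
#' @param copy_noise per-site mutation probability when emitting a gene copy
#'   from its species-family consensus (concerted-evolution jitter).
#' @param n_clusters number of gene clusters at the root.
#' @param families_per_cluster,copies_per_family integer vectors sampled
#'   uniformly per cluster/family.
#' @param anchor_within_prob probability of an anchor between two adjacent
#'   root genes inside a cluster.
#' @param gene_len,anchor_len,spacer element lengths in bp.
#' @param intron_prob probability that a family carries an intron.
#' @param intron_len_range inclusive range of intron lengths.
#' @param seed RNG seed; a fixed seed makes the output reproducible.
#' @export
sim_config <- function(tree = default_species_tree(),
                       rate_dup = 0.005, rate_loss = 0.005,
                       rate_seed = 0.15, rate_remold = 0.004,
                       rate_pseudo = 0.003, rate_anchor_loss = 0,
                       subst_rate = 0.01, copy_noise = 0.005,
                       n_clusters = 12, families_per_cluster = 2:3,
                       copies_per_family = 1:2, anchor_within_prob = 0.3,
                       gene_len = 73, anchor_len = 50, spacer = 100,
                       intron_prob = 0.15, intron_len_range = c(21, 52),
                       seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (n_clusters < 1) {
    stop("at least one anchored cluster is required: the synteny map needs anchors")
  }
  if (any(c(rate_dup, rate_loss, rate_seed, rate_remold, rate_pseudo,
            rate_anchor_loss) < 0)) {
    stop("rates must be non-negative")
  }
  mget(names(formals()))
}

.SENSE_ANTICODONS <- local({
  codons <- names(.GENETIC_CODE3)[.GENETIC_CODE3 != "Stop"]
  vapply(codons, function(cd) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(cd, "")[[1]]])), collapse = "")
  }, "", USE.NAMES = FALSE)
})

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_seq <- function(s, p) {
  if (p <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate gene cluster evolution with ground truth
#'
#' Genes evolve by single-gene tandem duplication, loss, seeding of new
#' loci, anticodon remolding and pseudogenization; anchors evolve only by
#' loss.  Coordinates are laid out by concatenating elements with fixed
#' spacers, so the coordinate map between any two species is exactly affine
#' between consecutive shared anchors.
#'
#' @param config see [sim_config()].
#' @return list with `genes` (gene table over all species), `anchors`
#'   (anchor placement table), `tree`, and `truth`: `edges` (true orthology
#'   relation), `graph` (`orthology_graph`, stage `"true"`, with the same
#'   synteny clusters the pipeline would use), `event_table` (the true
#'   history summarised with the same Dollo/cotree accounting applied to
#'   the true relation), `remoldings` (event log), `event_log` (all raw
#'   events), `lineages` (gene genealogy).
#' @export
simulate_evolution <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  # --- lineage registry -----------------------------------------------------
  lineages <- data.frame(lineage = character(0), parent = character(0),
                         family = character(0), birth = character(0),
                         birth_node = integer(0), stringsAsFactors = FALSE)
  lin_count <- 0L
  new_lineage <- function(parent, family, birth, birth_node) {
    lin_count <<- lin_count + 1L
    id <- sprintf("L%03d", lin_count)
    lineages[nrow(lineages) + 1L, ] <<-
      list(id, parent, family, birth, birth_node)
    id
  }

  fam_count <- 0L
  families <- list()   # family -> list(anticodon, intron, root_seq)
  new_family <- function() {
    fam_count <<- fam_count + 1L
    fid <- sprintf("F%02d", fam_count)
    has_intron <- stats::runif(1) < config$intron_prob
    ilen <- if (has_intron)
      sample(config$intron_len_range[1]:config$intron_len_range[2], 1) else 0
    families[[fid]] <<- list(
      anticodon = sample(.SENSE_ANTICODONS, 1),
      intron = if (has_intron) matrix(c(38, 38 + ilen), 1) else NULL,
      len = config$gene_len + ilen)
    fid
  }

  # --- root genome ----------------------------------------------------------
  anchor_count <- 0L
  new_anchor <- function() {
    anchor_count <<- anchor_count + 1L
    sprintf("A%03d", anchor_count)
  }
  elements <- list()  # each: list(kind, id, family, anticodon, pseudo)
  push <- function(el) elements[[length(elements) + 1L]] <<- el
  push(list(kind = "anchor", id = new_anchor()))
  for (cl in seq_len(config$n_clusters)) {
    nf <- sample(config$families_per_cluster, 1)
    first <- TRUE
    for (f in seq_len(nf)) {
      fid <- new_family()
      nc <- sample(config$copies_per_family, 1)
      for (cp in seq_len(nc)) {
        if (!first && stats::runif(1) < config$anchor_within_prob) {
          push(list(kind = "anchor", id = new_anchor()))
        }
        first <- FALSE
        push(list(kind = "gene",
                  id = new_lineage(NA_character_, fid, "root", root),
                  family = fid,
                  anticodon = families[[fid]]$anticodon,
                  pseudo = FALSE))
      }
    }
    push(list(kind = "anchor", id = new_anchor()))
  }

  fam_seq_root <- lapply(families, function(f) .random_seq(f$len))

  # --- evolution along the tree --------------------------------------------
  event_log <- list()
  remold_log <- list()
  log_event <- function(type, node, ...) {
    event_log[[length(event_log) + 1L]] <<-
      c(list(type = type, branch = node_key(tree, node)), list(...))
  }
  tips_out <- list()

  evolve <- function(node, elements, fam_seq) {
    kids <- .children(tree, node)
    if (length(kids) == 0) {
      tips_out[[tree$tip.label[node]]] <<- list(elements = elements,
                                                fam_seq = fam_seq)
      return(invisible())
    }
    for (ch in kids) {
      len <- tree$edge.length[which(tree$edge[, 2] == ch)]
      el <- elements
      fs <- lapply(fam_seq, .mutate_seq, p = config$subst_rate * len)

      gene_idx <- function() which(vapply(el, function(e) e$kind == "gene", TRUE))

      n_dup <- stats::rpois(1, config$rate_dup * len * length(gene_idx()))
      for (k in seq_len(n_dup)) {
        gi <- gene_idx(); if (length(gi) == 0) break
        i <- if (length(gi) == 1) gi else sample(gi, 1)
        src <- el[[i]]
        cp <- src
        cp$id <- new_lineage(src$id, src$family, node_key(tree, ch), ch)
        cp$pseudo <- FALSE
        el <- append(el, list(cp), after = i)
        log_event("duplication", ch, lineage = cp$id, source = src$id,
                  family = src$family)
      }
      n_loss <- stats::rpois(1, config$rate_loss * len * length(gene_idx()))
      for (k in seq_len(n_loss)) {
        gi <- gene_idx(); if (length(gi) == 0) break
        i <- if (length(gi) == 1) gi else sample(gi, 1)
        log_event("loss", ch, lineage = el[[i]]$id, family = el[[i]]$family)
        el[[i]] <- NULL
      }
      n_seed <- stats::rpois(1, config$rate_seed * len)
      for (k in seq_len(n_seed)) {
        fid <- new_family()
        fs[[fid]] <- .random_seq(families[[fid]]$len)
        pos <- sample(length(el) - 1, 1)  # between elements; ends are anchors
        g <- list(kind = "gene",
                  id = new_lineage(NA_character_, fid, node_key(tree, ch), ch),
                  family = fid, anticodon = families[[fid]]$anticodon,
                  pseudo = FALSE)
        el <- append(el, list(g), after = pos)
        log_event("seeding", ch, lineage = g$id, family = fid)
      }
      n_rem <- stats::rpois(1, config$rate_remold * len * length(gene_idx()))
      for (k in seq_len(n_rem)) {
        gi <- gene_idx(); if (length(gi) == 0) break
        i <- if (length(gi) == 1) gi else sample(gi, 1)
        ac <- el[[i]]$anticodon
        repeat {
          pos3 <- sample(3, 1)
          ch3 <- strsplit(ac, "")[[1]]
          ch3[pos3] <- sample(setdiff(c("A", "C", "G", "T"), ch3[pos3]), 1)
          nac <- paste(ch3, collapse = "")
          if (nac %in% .SENSE_ANTICODONS) break
        }
        log_event("remolding", ch, lineage = el[[i]]$id, from = ac, to = nac,
                  class = classify_remolding(ac, nac))
        remold_log[[length(remold_log) + 1L]] <<- data.frame(
          branch = node_key(tree, ch), lineage = el[[i]]$id,
          from = ac, to = nac, class = classify_remolding(ac, nac),
          stringsAsFactors = FALSE)
        el[[i]]$anticodon <- nac
      }
      n_ps <- stats::rpois(1, config$rate_pseudo * len * length(gene_idx()))
      for (k in seq_len(n_ps)) {
        gi <- gene_idx(); if (length(gi) == 0) break
        i <- if (length(gi) == 1) gi else sample(gi, 1)
        el[[i]]$pseudo <- TRUE
        log_event("pseudogenization", ch, lineage = el[[i]]$id)
      }
      n_al <- stats::rpois(1, config$rate_anchor_loss * len)
      for (k in seq_len(n_al)) {
        ai <- which(vapply(el, function(e) e$kind == "anchor", TRUE))
        if (length(ai) <= 2) break
        i <- if (length(ai) == 1) ai else sample(ai, 1)
        log_event("anchor_loss", ch, anchor = el[[i]]$id)
        el[[i]] <- NULL
      }
      evolve(ch, el, fs)
    }
  }
  evolve(root, elements, fam_seq_root)

  # --- emit coordinates, sequences, anchors --------------------------------
  gene_rows <- list(); anchor_rows <- list()
  for (sp in names(tips_out)) {
    st <- tips_out[[sp]]
    pos <- config$spacer
    for (e in st$elements) {
      if (e$kind == "anchor") {
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          anchor_id = e$id, species = sp, chrom = "chr1",
          start = pos, end = pos + config$anchor_len, strand = "+",
          stringsAsFactors = FALSE)
        pos <- pos + config$anchor_len + config$spacer
      } else {
        fam <- families[[e$family]]
        s <- .mutate_seq(st$fam_seq[[e$family]], config$copy_noise)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = paste0(sp, ".", e$id), species = sp, chrom = "chr1",
          start = pos, end = pos + fam$len, strand = "+",
          sequence = s, anticodon = e$anticodon,
          pseudogene = e$pseudo, family = e$family, lineage = e$id,
          stringsAsFactors = FALSE)
        pos <- pos + fam$len + config$spacer
      }
    }
  }
  genes <- do.call(rbind, gene_rows)
  genes$isoacceptor <- vapply(genes$anticodon, anticodon_to_aa, "")
  genes$introns <- lapply(genes$family, function(f) families[[f]]$intron)
  anc <- do.call(rbind, anchor_rows)
  nsp <- table(anc$anchor_id)
  anc <- anc[anc$anchor_id %in% names(nsp)[nsp >= 2], , drop = FALSE]
  anchors <- anchor_table(anc$anchor_id, anc$species, anc$chrom, anc$start,
                          anc$end, anc$strand)

  truth <- .ground_truth(genes, anchors, tree, lineages,
                         if (length(remold_log)) do.call(rbind, remold_log)
                         else NULL)
  truth$event_log <- event_log
  truth$lineages <- lineages

  list(genes = genes, anchors = anchors, tree = tree, truth = truth,
       config = config)
}

# True orthology from the gene genealogy: two extant genes of different
# species are (co-)orthologs iff every duplication separating their lineages
# happened below (after) the speciation at their species' last common
# ancestor.
.ground_truth <- function(genes, anchors, tree, lineages, remoldings) {
  anc_chain <- function(lin) {
    out <- character(0)
    while (!is.na(lin)) {
      out <- c(out, lin)
      lin <- lineages$parent[match(lin, lineages$lineage)]
    }
    out
  }
  chains <- lapply(stats::setNames(unique(genes$lineage), unique(genes$lineage)),
                   anc_chain)
  birth_node <- stats::setNames(lineages$birth_node, lineages$lineage)
  ntip <- length(tree$tip.label)
  # descendant node sets per internal node
  desc <- lapply(seq_len(ntip + tree$Nnode), function(n) {
    if (n <= ntip) return(integer(0))
    unlist(.node_descendants(tree, n))
  })
  mrca_cache <- new.env(parent = emptyenv())
  sp_mrca <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (!is.null(mrca_cache[[k]])) return(mrca_cache[[k]])
    v <- ape::getMRCA(tree, c(a, b))
    mrca_cache[[k]] <- v
    v
  }
  tipnum <- stats::setNames(seq_len(ntip), tree$tip.label)

  edges <- list()
  n <- nrow(genes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (genes$species[i] == genes$species[j]) next
      u <- genes$lineage[i]; v <- genes$lineage[j]
      cu <- chains[[u]]; cv <- chains[[v]]
      common <- intersect(cu, cv)
      if (length(common) == 0) next  # different origins: not homologous loci
      w <- common[1]                 # deepest shared lineage (chains are
                                     # ordered self -> root, so first common)
      s <- sp_mrca(genes$species[i], genes$species[j])
      below_s <- desc[[s]]
      ok <- TRUE
      for (chain in list(cu, cv)) {
        k <- match(w, chain)
        if (k > 1) {
          branch_child <- birth_node[chain[k - 1]]
          if (!(branch_child %in% below_s)) ok <- FALSE
        }
      }
      if (ok) {
        edges[[length(edges) + 1]] <- data.frame(
          from = genes$gene_id[i], to = genes$gene_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  E <- canonical_edges(if (length(edges)) do.call(rbind, edges) else NULL)
  fl <- gene_flanks(genes, anchors)
  flag <- ifelse(is.na(fl$left_anchor) | is.na(fl$right_anchor), "missing", "ok")
  clusters <- data.frame(gene_id = genes$gene_id,
                         cluster_id = ifelse(flag == "ok",
                                             paste(fl$left_anchor, fl$right_anchor, sep = "|"),
                                             paste0("orphan:", genes$gene_id)),
                         flag = flag, left_anchor = fl$left_anchor,
                         right_anchor = fl$right_anchor,
                         stringsAsFactors = FALSE)
  gtruth <- orthology_graph(genes, E, "true", clusters)
  ev <- summarize_events(gtruth, tree)
  list(edges = E, graph = gtruth, event_table = ev$table,
       components = ev$components,
       remoldings = if (is.null(remoldings))
         data.frame(branch = character(0), lineage = character(0),
                    from = character(0), to = character(0),
                    class = character(0), stringsAsFactors = FALSE)
       else remoldings)
}

# all descendant node numbers of an internal node (tips and internals)
.node_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- .children(tree, node)
  while (length(stack) > 0) {
    x <- stack[1]; stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, .children(tree, x))
  }
  out
}

#' Score a reconstruction against simulator ground truth
#'
#' @param truth the `truth` element of [simulate_evolution()] output.
#' @param graph reconstructed `orthology_graph`.
#' @param event_table reconstructed per-branch event table (optional).
#' @param remoldings reconstructed remolding table (optional).
#' @return list with `edge_precision`, `edge_recall`, `edge_f1`, counts
#'   (`tp`, `fp`, `fn`), `event_deltas` (per-branch signed estimate minus
#'   truth for gains/duplications/losses) and `remolding_recovery` (fraction
#'   of true events recovered as an unordered anticodon pair with matching
#'   class), `NA` when not assessed.
#' @export
score_reconstruction <- function(truth, graph, event_table = NULL,
                                 remoldings = NULL) {
  cmp <- graph_compare(truth$edges, graph)
  tp <- nrow(cmp$shared); fn <- nrow(cmp$only_g1); fp <- nrow(cmp$only_g2)
  prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  deltas <- NULL
  if (!is.null(event_table)) {
    m <- merge(truth$event_table, event_table, by = "branch",
               suffixes = c("_true", "_est"))
    deltas <- data.frame(
      branch = m$branch,
      gains = m$gains_seeding_est - m$gains_seeding_true,
      duplications = m$duplications_est - m$duplications_true,
      losses = m$losses_est - m$losses_true,
      stringsAsFactors = FALSE)
  }
  rr <- NA_real_
  if (!is.null(remoldings) && nrow(truth$remoldings) > 0) {
    pair_key <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to),
                                   df$class)
    rr <- mean(pair_key(truth$remoldings) %in% pair_key(remoldings))
  }
  list(edge_precision = prec, edge_recall = rec, edge_f1 = f1,
       tp = tp, fp = fp, fn = fn,
       event_deltas = deltas, remolding_recovery = rr)
}
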