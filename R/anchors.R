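# Synteny anchors: cleaning of alignment blocks, protein-pair anchors,
# tight anchor pairs and linear coordinate interpolation.

#' Construct an anchor table
#'
#' An anchor is a uniquely aligned, 1:1-orthologous interval placed in two or
#' more species; anchors are the positional landmarks from which synteny is
#' read.  The table holds one row per placement.
#'
#' @param anchor_id anchor identifier (repeated across its placements).
#' @param species,chrom,start,end,strand placement coordinates.
#' @return a sorted placement `data.frame`.
#' @export
anchor_table <- function(anchor_id, species, chrom, start, end, strand = "+") {
  df <- genomic_intervals(species, chrom, start, end, strand)
  df <- cbind(anchor_id = as.character(anchor_id), df)
  tab <- table(unique(df[c("anchor_id", "species")])$anchor_id)
  if (any(tab < 2)) {
    warning(sprintf("%d anchor(s) placed in fewer than 2 species", sum(tab < 2)))
  }
  sort_placements(df)
}

#' Clean alignment blocks into usable anchors
#'
#' Alignment pipelines may place the same sequence in several blocks
#' (typically at duplicated regions), which disqualifies those blocks as
#' synteny anchors.  A block is retained only if, in every species it covers,
#' it overlaps neither a tRNA locus nor any other block (retained or not).
#'
#' @param blocks placement `data.frame` with columns `block_id`, `species`,
#'   `chrom`, `start`, `end`, `strand` (e.g. from [parse_maf()]).
#' @param trna_loci interval `data.frame` of annotated tRNA loci.
#' @return an anchor placement table (`anchor_id` = `block_id`), sorted per
#'   species and coordinate.
#' @export
clean_maf_blocks <- function(blocks, trna_loci = NULL) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(anchor_empty())
  }
  # reject malformed placements (start >= end) block-wise, not fatally
  bad <- blocks$start >= blocks$end
  if (any(bad)) {
    bad_ids <- unique(blocks$block_id[bad])
    warning(sprintf("dropping %d block(s) with inconsistent spans: %s",
                    length(bad_ids), paste(utils::head(bad_ids, 5), collapse = ", ")))
    blocks <- blocks[!(blocks$block_id %in% bad_ids), , drop = FALSE]
    if (nrow(blocks) == 0) return(anchor_empty())
  }
  drop <- character(0)
  for (key in unique(paste(blocks$species, blocks$chrom))) {
    sel <- paste(blocks$species, blocks$chrom) == key
    b <- blocks[sel, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1) {
      # sweep: a block overlaps its successor iff end > next start
      ov <- b$end[-nrow(b)] > b$start[-1]
      if (any(ov)) {
        drop <- c(drop, b$block_id[c(which(ov), which(ov) + 1L)])
      }
    }
    if (!is.null(trna_loci) && nrow(trna_loci) > 0) {
      tl <- trna_loci[paste(trna_loci$species, trna_loci$chrom) == key, , drop = FALSE]
      if (nrow(tl) > 0) {
        hit <- vapply(seq_len(nrow(b)), function(i) {
          any(.overlaps(b$start[i], b$end[i], tl$start, tl$end))
        }, logical(1))
        drop <- c(drop, b$block_id[hit])
      }
    }
  }
  keep <- blocks[!(blocks$block_id %in% drop), , drop = FALSE]
  # an anchor must connect at least two species
  nsp <- tapply(keep$species, keep$block_id, function(s) length(unique(s)))
  keep <- keep[keep$block_id %in% names(nsp)[nsp >= 2], , drop = FALSE]
  if (nrow(keep) == 0) return(anchor_empty())
  anchor_table(keep$block_id, keep$species, keep$chrom, keep$start, keep$end,
               keep$strand)
}

anchor_empty <- function() {
  data.frame(anchor_id = character(0), species = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Filter orthologous protein pairs by alignment chains
#'
#' Many-to-many co-ortholog annotations are resolved against alignment
#' chains: a pair is retained only if some chain block contains both members,
#' and any gene participating in more than one retained pair is discarded so
#' that the result is strictly 1:1.  Retained pairs become two-species
#' anchors.
#'
#' @param pairs `data.frame` with columns `id_a`, `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `id_b`, `species_b`, `chrom_b`, `start_b`, `end_b`.
#' @param chains chain block `data.frame` with columns `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`
#'   (e.g. from [parse_chain()]).
#' @return an anchor placement table.
#' @export
filter_protein_orthologs <- function(pairs, chains) {
  if (is.null(pairs) || nrow(pairs) == 0) return(anchor_empty())
  contains <- function(cs, ce, gs, ge) cs <= gs & ge <= ce
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    same <- chains$species_a == p$species_a & chains$chrom_a == p$chrom_a &
      chains$species_b == p$species_b & chains$chrom_b == p$chrom_b &
      contains(chains$start_a, chains$end_a, p$start_a, p$end_a) &
      contains(chains$start_b, chains$end_b, p$start_b, p$end_b)
    swap <- chains$species_a == p$species_b & chains$chrom_a == p$chrom_b &
      chains$species_b == p$species_a & chains$chrom_b == p$chrom_a &
      contains(chains$start_a, chains$end_a, p$start_b, p$end_b) &
      contains(chains$start_b, chains$end_b, p$start_a, p$end_a)
    any(same) || any(swap)
  }, logical(1))
  ret <- pairs[keep, , drop = FALSE]
  if (nrow(ret) == 0) return(anchor_empty())
  # enforce 1:1 within each species pair: drop genes occurring in more than
  # one retained pair for that pair of species
  grp <- paste(ret$species_a, ret$species_b)
  ka <- paste(grp, ret$id_a)
  kb <- paste(grp, ret$id_b)
  multi <- c(ka[duplicated(ka)], kb[duplicated(kb)])
  ok <- !(ka %in% multi) & !(kb %in% multi)
  ret <- ret[ok, , drop = FALSE]
  if (nrow(ret) == 0) return(anchor_empty())
  aid <- paste0(ret$id_a, "~", ret$id_b)
  anchor_table(
    anchor_id = c(aid, aid),
    species = c(ret$species_a, ret$species_b),
    chrom = c(ret$chrom_a, ret$chrom_b),
    start = c(ret$start_a, ret$start_b),
    end = c(ret$end_a, ret$end_b)
  )
}

#' Tight anchor pair of a gene into a target species
#'
#' The tight anchors of a query gene into species `b` are the nearest anchors
#' flanking the gene in the query species that are also placed in `b`; by the
#' synteny assumptions they delimit all possible (co-)orthologs of the gene
#' in `b`.  Anchors without a placement in the target species are skipped.
#'
#' @param gene one-row `data.frame` (or list) with `species`, `chrom`,
#'   `start`, `end`.
#' @param target target species identifier.
#' @param anchors anchor placement table.
#' @return a list with elements `left`, `right` (anchor ids or `NA`),
#'   `status` (`"ok"`, `"missing"` when a side has no anchor, `"split"` when
#'   the two anchors map to different target chromosomes) and
#'   `target_chrom`.
#' @export
tight_anchor_pair <- function(gene, target, anchors) {
  g <- as.list(as.data.frame(gene)[1, ])
  cand <- anchors[anchors$species == g$species & anchors$chrom == g$chrom, , drop = FALSE]
  placed <- unique(anchors$anchor_id[anchors$species == target])
  cand <- cand[cand$anchor_id %in% placed, , drop = FALSE]
  left <- right <- NA_character_
  if (nrow(cand) > 0) {
    lf <- cand[cand$end <= g$start, , drop = FALSE]
    if (nrow(lf) > 0) left <- lf$anchor_id[which.max(lf$end)]
    rt <- cand[cand$start >= g$end, , drop = FALSE]
    if (nrow(rt) > 0) right <- rt$anchor_id[which.min(rt$start)]
  }
  status <- "ok"
  target_chrom <- NA_character_
  if (is.na(left) || is.na(right)) {
    status <- "missing"
  } else {
    tl <- anchors[anchors$anchor_id == left & anchors$species == target, , drop = FALSE]
    tr <- anchors[anchors$anchor_id == right & anchors$species == target, , drop = FALSE]
    if (tl$chrom[1] != tr$chrom[1]) status <- "split" else target_chrom <- tl$chrom[1]
  }
  list(left = left, right = right, status = status, target_chrom = target_chrom)
}

#' Linear coordinate interpolation between anchor points
#'
#' Estimates the position of a locus in a target genome from its offset to
#' the left anchor, scaled by the ratio of the inter-anchor span lengths in
#' the two genomes.  Exact whenever the coordinate map between the anchors is
#' affine; in particular it is the identity when both genomes agree.
#'
#' @param t_a query-genome coordinate of the locus (one end of the gene).
#' @param p_a,q_a left/right anchor points in the query genome (`p_a < q_a`).
#' @param p_b,q_b the corresponding anchor points in the target genome.
#' @return the estimated target coordinate (fractional positions allowed).
#' @export
interpolate_position <- function(t_a, p_a, q_a, p_b, q_b) {
  if (q_a <= p_a || q_b <= p_b) {
    stop("non-positive inter-anchor span: corrupt anchor pair")
  }
  p_b + (q_b - p_b + 1) / (q_a - p_a + 1) * (t_a - p_a)
}

# Interpolate both ends of a gene through a tight anchor pair.
# Anchor points are the gene-facing boundaries of the flanking anchors.
interpolate_gene <- function(gene, pair, target, anchors) {
  g <- as.list(as.data.frame(gene)[1, ])
  qa_l <- anchors[anchors$anchor_id == pair$left & anchors$species == g$species, ][1, ]
  qa_r <- anchors[anchors$anchor_id == pair$right & anchors$species == g$species, ][1, ]
  tb_l <- anchors[anchors$anchor_id == pair$left & anchors$species == target, ][1, ]
  tb_r <- anchors[anchors$anchor_id == pair$right & anchors$species == target, ][1, ]
  p_a <- qa_l$end; q_a <- qa_r$start
  p_b <- tb_l$end; q_b <- tb_r$start
  c(
    end5 = interpolate_position(g$start, p_a, q_a, p_b, q_b),
    end3 = interpolate_position(g$end, p_a, q_a, p_b, q_b)
  )
}

# Nearest gene to an estimated position; ties resolved toward the gene 5' of
# the position (deterministic).
.nearest_gene <- function(pos, genes) {
  if (nrow(genes) == 0) return(NA_character_)
  mid <- (genes$start + genes$end) / 2
  d <- abs(mid - pos)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(mid[best])]
  genes$gene_id[best]
}

#' 1:1 orthologs by reciprocal coordinate interpolation
#'
#' For each query gene, the `k_proteins` nearest anchors shared with the
#' target species provide a tight flanking pair; the gene's 5' and 3' ends
#' are interpolated into the target and the nearest target gene is proposed.
#' A pair is emitted only when proposed reciprocally in both directions.
#' Genes whose 5'- and 3'-end interpolations disagree on the nearest target
#' gene are dropped.  This route detects 1:1 orthologs only; co-orthologs
#' from duplications are out of its reach by construction.
#'
#' @param genes_a,genes_b gene tables of the two species.
#' @param anchors anchor placement table.
#' @param k_proteins number of nearest anchors considered per gene.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
interpolation_orthologs <- function(genes_a, genes_b, anchors, k_proteins = 10) {
  propose <- function(ga, gb) {
    tsp <- gb$species[1]
    out <- character(nrow(ga))
    for (i in seq_len(nrow(ga))) {
      g <- ga[i, ]
      cand <- anchors[anchors$species == g$species & anchors$chrom == g$chrom, , drop = FALSE]
      cand <- cand[cand$anchor_id %in% anchors$anchor_id[anchors$species == tsp], , drop = FALSE]
      out[i] <- NA_character_
      if (nrow(cand) == 0) next
      mid <- (g$start + g$end) / 2
      cand <- cand[order(abs((cand$start + cand$end) / 2 - mid)), , drop = FALSE]
      cand <- utils::head(cand, k_proteins)
      pr <- tight_anchor_pair(g, tsp,
                              anchors[anchors$anchor_id %in% cand$anchor_id, ,
                                      drop = FALSE])
      if (pr$status != "ok") next
      est <- interpolate_gene(g, pr, tsp, anchors)
      tg <- gb[gb$chrom == pr$target_chrom, , drop = FALSE]
      hit5 <- .nearest_gene(est["end5"], tg)
      hit3 <- .nearest_gene(est["end3"], tg)
      if (!is.na(hit5) && identical(hit5, hit3)) out[i] <- hit5
    }
    data.frame(gene_a = ga$gene_id, gene_b = out, stringsAsFactors = FALSE)
  }
  ab <- propose(genes_a, genes_b)
  ba <- propose(genes_b, genes_a)
  ab <- ab[!is.na(ab$gene_b), , drop = FALSE]
  ba <- ba[!is.na(ba$gene_b), , drop = FALSE]
  key_ab <- paste(ab$gene_a, ab$gene_b)
  key_ba <- paste(ba$gene_b, ba$gene_a)
  res <- ab[key_ab %in% key_ba, , drop = FALSE]
  rownames(res) <- NULL
  res
}
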