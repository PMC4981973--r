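# Readers and writers: MAF alignment blocks, UCSC chains, BED6, tRNAscan-SE
# tabular output, and the package's own TSV artifacts.  All coordinates are
# normalized to 0-based half-open forward-strand intervals at parse time.

#' Parse a MAF file into per-species alignment block placements
#'
#' Reverse-strand records are converted to forward-strand coordinates
#' (`start' = srcSize - start - size`).  The `src` field is split at the
#' first dot into species and chromosome.
#'
#' @param path MAF file path.
#' @return `data.frame` with columns `block_id`, `species`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
parse_maf <- function(path) {
  lines <- readLines(path)
  rows <- list()
  block <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "a")) { block <- block + 1L; next }
    if (!startsWith(line, "s")) next
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(f) < 7) stop(sprintf("malformed MAF 's' line at line %d", ln))
    start <- suppressWarnings(as.numeric(f[3]))
    size <- suppressWarnings(as.numeric(f[4]))
    srcsize <- suppressWarnings(as.numeric(f[6]))
    if (anyNA(c(start, size, srcsize))) {
      stop(sprintf("non-numeric MAF coordinate field at line %d", ln))
    }
    if (block == 0L) stop(sprintf("'s' line before any 'a' line at line %d", ln))
    src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
    if (length(src) < 2) stop(sprintf("MAF src without species.chrom at line %d", ln))
    fwd_start <- if (f[5] == "-") srcsize - start - size else start
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = sprintf("B%04d", block),
      species = src[1], chrom = paste(src[-1], collapse = "."),
      start = fwd_start, end = fwd_start + size, strand = f[5],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(block_id = character(0), species = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write anchors as a MAF-like file
#'
#' Each anchor becomes one alignment block; sequence text is a placeholder
#' run of `N`s (the pipeline only consumes coordinates).
#'
#' @param anchors anchor placement table.
#' @param path output path.
#' @export
write_anchor_maf <- function(anchors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (aid in unique(anchors$anchor_id)) {
    rows <- anchors[anchors$anchor_id == aid, , drop = FALSE]
    writeLines(sprintf("a score=0 # %s", aid), con)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      writeLines(sprintf("s %s.%s %d %d + %d %s",
                         r$species, r$chrom, r$start, r$end - r$start,
                         max(r$end, 10000000),
                         strrep("N", min(r$end - r$start, 60))), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Parse a UCSC chain file into paired block intervals
#'
#' Walks the per-chain block list and emits one row per gap-free aligned
#' block.  Reverse-strand query coordinates are converted to forward-strand.
#'
#' @param path chain file path.
#' @param species_a,species_b species labels for the target (first) and
#'   query (second) genome of the chain file.
#' @return `data.frame` with columns `species_a`, `chrom_a`, `start_a`,
#'   `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`.
#' @export
parse_chain <- function(path, species_a, species_b) {
  lines <- readLines(path)
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!startsWith(line, "chain")) { i <- i + 1L; next }
    h <- strsplit(line, "[ \t]+")[[1]]
    if (length(h) < 12) stop(sprintf("malformed chain header at line %d", i))
    tname <- h[3]; tstrand <- h[5]; tstart <- as.numeric(h[6])
    qname <- h[8]; qsize <- as.numeric(h[9]); qstrand <- h[10]
    qstart <- as.numeric(h[11])
    tpos <- tstart; qpos <- qstart
    i <- i + 1L
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
      if (anyNA(f)) stop(sprintf("non-numeric chain block at line %d", i))
      size <- f[1]
      qs <- if (qstrand == "-") qsize - (qpos + size) else qpos
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = species_a, chrom_a = tname,
        start_a = tpos, end_a = tpos + size,
        species_b = species_b, chrom_b = qname,
        start_b = qs, end_b = qs + size, stringsAsFactors = FALSE)
      if (length(f) == 3) { tpos <- tpos + size + f[2]; qpos <- qpos + size + f[3] }
      i <- i + 1L
    }
    i <- i + 1L
  }
  if (length(rows) == 0) {
    return(data.frame(species_a = character(0), chrom_a = character(0),
                      start_a = numeric(0), end_a = numeric(0),
                      species_b = character(0), chrom_b = character(0),
                      start_b = numeric(0), end_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a BED6 file of intervals for one species
#'
#' @param path BED file path.
#' @param species species label to attach.
#' @return interval `data.frame` with `name` and `score` columns.
#' @export
read_bed6 <- function(path, species) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    species = species,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", "+",
                    as.character(GenomicRanges::strand(gr))),
    name = if (is.null(gr$name)) NA_character_ else gr$name,
    score = if (is.null(gr$score)) 0 else as.numeric(gr$score),
    stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df interval `data.frame` (columns `chrom`, `start`, `end`,
#'   `strand`, optionally `name`, `score`).
#' @param path output path.
#' @export
write_bed6 <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$name <- if ("name" %in% names(df)) df$name else
    if ("gene_id" %in% names(df)) df$gene_id else
      if ("anchor_id" %in% names(df)) df$anchor_id else "."
  gr$score <- if ("score" %in% names(df)) df$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Parse tRNAscan-SE tabular output
#'
#' Accepts the common tabular layout (name, tRNA number, begin, end,
#' isotype, anticodon, intron begin/end, score, optional note).  Input
#' coordinates are 1-based inclusive with strand implied by coordinate
#' order; they are normalized to 0-based half-open forward-strand intervals
#' and intron bounds become intervals relative to the gene's 5' end.  Rows
#' whose note contains "pseudo" are flagged as pseudogenes; unknown isotype
#' tokens yield isoacceptor "Undet" with a warning.
#'
#' @param path file path.
#' @param species species label to attach.
#' @return a gene table (see [trna_genes()]); the `anticodon` column keeps
#'   the reported anticodon, `isoacceptor` the reported isotype.
#' @export
parse_trnascan <- function(path, species) {
  lines <- readLines(path)
  # skip the standard 3-line header if present
  hdr <- grep("^-+", lines)
  if (length(hdr) > 0) lines <- lines[-seq_len(hdr[1])]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(trna_genes(character(0), character(0), character(0),
                      numeric(0), numeric(0)))
  }
  known <- c(unique(unname(.GENETIC_CODE3)), "SeC", "Sup", "Undet", "Pseudo")
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 9) stop(sprintf("malformed tRNAscan row %d", i))
    begin <- as.numeric(f[3]); end <- as.numeric(f[4])
    strand <- if (begin <= end) "+" else "-"
    lo <- min(begin, end) - 1; hi <- max(begin, end)
    iso <- f[5]
    if (!(iso %in% known)) {
      warning(sprintf("unknown isotype '%s' in row %d; set to Undet", iso, i))
      iso <- "Undet"
    }
    ac <- toupper(f[6])
    if (grepl("[^ACGT]", ac)) ac <- NA_character_
    ib <- as.numeric(f[7]); ie <- as.numeric(f[8])
    intr <- NULL
    if (!is.na(ib) && !is.na(ie) && ib != 0 && ie != 0) {
      if (strand == "+") intr <- matrix(c(ib - begin, ie - begin + 1), 1)
      else intr <- matrix(c(begin - ie, begin - ib + 1), 1)
    }
    pseudo <- length(f) >= 10 && grepl("pseudo", paste(f[-(1:9)], collapse = " "),
                                       ignore.case = TRUE)
    list(id = sprintf("%s.%s.trna%s", species, f[1], f[2]),
         chrom = f[1], start = lo, end = hi, strand = strand,
         anticodon = ac, iso = iso, pseudo = pseudo, intron = intr)
  })
  g <- trna_genes(
    id = vapply(out, `[[`, "", "id"),
    species = species,
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    anticodon = vapply(out, function(x) x$anticodon, ""),
    pseudogene = vapply(out, `[[`, TRUE, "pseudo"),
    introns = lapply(out, `[[`, "intron"))
  g$isoacceptor <- vapply(out, `[[`, "", "iso")
  g
}

# ---- TSV artifacts --------------------------------------------------------

#' Write an anchor table as TSV
#' @param anchors anchor placement table.
#' @param path output path.
#' @export
write_anchors_tsv <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an anchor table from TSV
#' @param path input path.
#' @export
read_anchors_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric", "character"),
                    stringsAsFactors = FALSE)
}

#' Write an orthology graph's edges as TSV with a stage header
#' @param g an `orthology_graph`.
#' @param path output path.
#' @export
write_edges_tsv <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s", g$stage), con)
  utils::write.table(g$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge TSV written by [write_edges_tsv()]
#' @param path input path.
#' @return list with `edges` and `stage`.
#' @export
read_edges_tsv <- function(path) {
  first <- readLines(path, n = 1)
  stage <- sub("^# stage=", "", first)
  edges <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  list(edges = edges, stage = stage)
}

#' Write the synteny cluster table as TSV
#' @param g an `orthology_graph`.
#' @param path output path.
#' @export
write_clusters_tsv <- function(g, path) {
  cl <- merge(g$clusters, g$genes[c("gene_id", "species", "start")],
              by = "gene_id")
  cl <- cl[order(cl$cluster_id, cl$species, cl$start), ]
  cl$order_index <- stats::ave(seq_len(nrow(cl)),
                               paste(cl$cluster_id, cl$species),
                               FUN = seq_along)
  utils::write.table(
    cl[c("cluster_id", "gene_id", "species", "order_index", "flag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-branch event table as TSV
#' @param table event table from [summarize_events()].
#' @param path output path.
#' @export
write_event_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a remolding event list as TSV
#' @param remoldings table from [detect_remoldings()].
#' @param path output path.
#' @export
write_remoldings_tsv <- function(remoldings, path) {
  utils::write.table(remoldings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
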