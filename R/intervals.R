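#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end), forward
# strand coordinates.  Readers for 1-based or reverse-strand formats convert
# at parse time so that all downstream order comparisons use one convention.

#' Construct a table of genomic intervals
#'
#' Intervals are the common currency of the package: anchors, genes and
#' alignment blocks are all placed as intervals.  Coordinates are 0-based and
#' half-open.
#'
#' @param species character vector of species identifiers.
#' @param chrom character vector of chromosome/contig identifiers.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand character vector, `"+"` or `"-"`.
#' @return a `data.frame` with columns `species`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
genomic_intervals <- function(species, chrom, start, end, strand = "+") {
  df <- data.frame(
    species = as.character(species),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(species)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("species", "chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- df$start >= df$end
  if (any(bad)) {
    stop(sprintf("%s with start >= end (rows %s)", what,
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  if (any(!nzchar(df$chrom))) stop(sprintf("%s with empty chrom", what))
  invisible(df)
}

# TRUE where [s1,e1) and [s2,e2) overlap
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Construct a tRNA gene table
#'
#' @param id gene identifiers (unique).
#' @param species,chrom,start,end,strand locus coordinates (0-based half-open).
#' @param sequence gene sequences (forward-strand gene sequence, 5' to 3').
#' @param anticodon 3-letter anticodon (DNA alphabet), or `NA`.
#' @param pseudogene logical pseudogene flag.
#' @param introns list of two-column matrices (`start`, `end`, relative to the
#'   gene 5' end, half-open) or `NULL` entries for intronless genes.
#' @return a `data.frame`, one row per gene, with an `isoacceptor` column
#'   derived from the anticodon under the standard genetic code.
#' @export
trna_genes <- function(id, species, chrom, start, end, strand = "+",
                       sequence = NA_character_, anticodon = NA_character_,
                       pseudogene = FALSE, introns = NULL) {
  n <- length(id)
  df <- data.frame(
    gene_id = as.character(id),
    species = rep_len(as.character(species), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    sequence = rep_len(as.character(sequence), n),
    anticodon = rep_len(toupper(as.character(anticodon)), n),
    pseudogene = rep_len(as.logical(pseudogene), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  validate_intervals(df, "gene")
  df$isoacceptor <- rep("Undet", n)
  ok <- !is.na(df$anticodon)
  if (any(ok)) df$isoacceptor[ok] <- vapply(df$anticodon[ok], anticodon_to_aa, "")
  df$introns <- if (is.null(introns)) vector("list", n) else introns
  df
}

# Sort a placement table by species, chrom, start.
sort_placements <- function(df) {
  df[order(df$species, df$chrom, df$start), , drop = FALSE]
}
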