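#' @title Gene-model containers
#' @description Lightweight S3 containers for transcripts and genes. All
#'   coordinates are internal convention: 0-based, half-open `[start, end)`,
#'   like BED. GTF/GFF3 1-based inclusive coordinates are converted at the
#'   I/O boundary and nowhere else.
#' @name models
NULL

#' Construct a transcript
#'
#' A transcript is an ordered chain of non-overlapping exons on one
#' chromosome and strand. Exons are stored in genomic order regardless of
#' strand; transcription order is derived from `strand` where it matters.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column `data.frame` (`start`, `end`), 0-based half-open.
#' @param attributes Named character vector of original annotation
#'   attributes, preserved verbatim.
#' @return An object of class `exon_transcript`.
#' @export
new_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           attributes = c(gene_id = gene_id,
                                          transcript_id = transcript_id)) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L)
    stop("transcript '", transcript_id, "' has no exons")
  if (any(exons$start < 0L) || any(exons$end <= exons$start))
    stop("transcript '", transcript_id,
         "' has an exon violating 0 <= start < end")
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript '", transcript_id, "' has overlapping exons")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 attributes = attributes),
            class = "exon_transcript")
}

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param transcripts List of [new_transcript()] objects sharing one
#'   chromosome and strand. Mixed strands/chromosomes are rejected, not
#'   repaired: classification semantics are undefined for them.
#' @return An object of class `gene_model`.
#' @export
new_gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) < 1L)
    stop("gene '", gene_id, "' has no transcripts")
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L)
    stop("gene '", gene_id, "' spans multiple chromosomes: ",
         paste(chroms, collapse = ", "))
  if (length(strands) != 1L)
    stop("gene '", gene_id, "' mixes strands")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, chrom = chroms, strand = strands,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Introns of a transcript
#'
#' Gaps between consecutive exons, derived deterministically; 0-based
#' half-open, genomic order.
#'
#' @param tx An `exon_transcript`.
#' @return `data.frame` with columns `start`, `end` (0 rows for
#'   single-exon transcripts).
#' @export
introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n], end = ex$start[-1L])
}

#' @export
print.exon_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s:%s %d exon(s)>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s %s:%s, %d transcript(s): %s>\n", x$gene_id, x$chrom,
              x$strand, length(x$transcripts),
              paste(names(x$transcripts), collapse = ", ")))
  invisible(x)
}

# Span of a gene over all its exons.
gene_span <- function(gene) {
  starts <- unlist(lapply(gene$transcripts, function(t) t$exons$start))
  ends <- unlist(lapply(gene$transcripts, function(t) t$exons$end))
  c(start = min(starts), end = max(ends))
}

# Distinct exon coordinate tuples of a gene, genomic order.
exon_units <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, function(t) t$exons))
  ex <- unique(ex)
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Reverse complement of a DNA string
#'
#' Plain-character helper over the `{A,C,G,T,N}` alphabet (case-folded).
#'
#' @param seq Single character string.
#' @return Reverse-complemented uppercase string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]]),
                 collapse = ""), "", USE.NAMES = FALSE))
}

#' GC fraction of a sequence
#'
#' Returns `NA` for windows containing `N` (missing-value convention for
#' ambiguous genome sequence) and for empty input.
#'
#' @param seq Single character string over `{A,C,G,T,N}`.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L || grepl("N", seq, fixed = TRUE))
    return(NA_real_)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(chars %in% c("G", "C"))
}

# Substring of a genome store sequence, 0-based half-open; errors if the
# window runs off the contig.
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("sequence '", chrom, "' not in genome")
  L <- nchar(genome[[chrom]])
  if (start < 0L || end > L)
    stop("window [", start, ",", end, ") off contig '", chrom,
         "' (length ", L, ")")
  substr(genome[[chrom]], start + 1L, end)
}
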