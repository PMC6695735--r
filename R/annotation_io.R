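#' @title Annotation and genome I/O
#' @description Readers for GTF/GFF3 gene models and FASTA genomes, writers
#'   for BED-like classification records and GTF round-tripping. All
#'   conversion between the external 1-based inclusive convention and the
#'   internal 0-based half-open convention happens here.
#' @name annotation_io
NULL

# Parse one attribute field. Accepts GTF (`key "value";`) and GFF3
# (`key=value;`) dialects; returns a named character vector in input order.
parse_attributes <- function(field, dialect) {
  field <- sub("[;[:space:]]+$", "", trimws(field))
  if (field == "" || field == ".")
    return(character(0))
  if (dialect == "gff3") {
    parts <- strsplit(field, ";", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(trimws(parts))]
    kv <- strsplit(trimws(parts), "=", fixed = TRUE)
    vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
    names(vals) <- vapply(kv, `[[`, "", 1L)
  } else {
    # GTF: key "value"; pairs (unquoted numeric values tolerated)
    m <- gregexpr('(\\S+)\\s+("[^"]*"|[^;]+);?', field)
    toks <- regmatches(field, m)[[1L]]
    keys <- sub('^\\s*(\\S+)\\s+.*$', "\\1", toks)
    vals <- sub('^\\s*\\S+\\s+("?)([^";]*)\\1;?\\s*$', "\\2", toks)
    names(vals) <- keys
  }
  vals
}

format_attributes_gtf <- function(attrs) {
  if (length(attrs) == 0L)
    return(".")
  paste0(names(attrs), ' "', attrs, '";', collapse = " ")
}

#' Read gene models from GTF or GFF3
#'
#' Only `exon` features are used; each must carry gene and transcript
#' identifiers (`gene_id`/`transcript_id` attributes; for GFF3, `Parent` is
#' accepted in place of `transcript_id`). External 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' Attributes are preserved verbatim on each transcript.
#'
#' @param path Annotation file.
#' @param dialect `"auto"` (by extension, default), `"gtf"`, or `"gff3"`.
#' @return List of [new_gene_model()] objects, sorted by `gene_id`.
#' @export
read_gene_models <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#"))
      next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (tolower(f[3L]) != "exon")
      next
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1))
      stop("malformed line ", i, ": non-numeric coordinates")
    if (end1 < start1)
      stop("malformed line ", i, ": end (", end1, ") < start (", start1, ")")
    if (!f[7L] %in% c("+", "-"))
      stop("malformed line ", i, ": strand must be '+' or '-', got '",
           f[7L], "'")
    attrs <- parse_attributes(f[9L], dialect)
    get_attr <- function(key)
      if (key %in% names(attrs)) unname(attrs[[key]]) else NA_character_
    tid <- get_attr("transcript_id")
    if (is.na(tid))
      tid <- sub("^transcript:", "", get_attr("Parent"))
    gid <- get_attr("gene_id")
    if (is.na(gid))
      gid <- get_attr("gene")
    if (is.na(tid))
      stop("line ", i, ": exon lacks a transcript identifier")
    if (is.na(gid))
      stop("line ", i, ": exon lacks a gene identifier")
    rows[[length(rows) + 1L]] <- list(
      chrom = f[1L], start = start1 - 1L, end = end1, strand = f[7L],
      gene_id = gid, transcript_id = tid, attrs = list(attrs))
  }
  if (length(rows) == 0L)
    return(list())
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, gene_id = r$gene_id,
               transcript_id = r$transcript_id)))
  attr_by_tx <- tapply(seq_len(nrow(tab)), tab$transcript_id,
                       function(idx) rows[[idx[1L]]]$attrs[[1L]])
  genes <- list()
  for (gid in sort(unique(tab$gene_id))) {
    gtab <- tab[tab$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in sort(unique(gtab$transcript_id))) {
      ttab <- gtab[gtab$transcript_id == tid, , drop = FALSE]
      if (length(unique(ttab$strand)) != 1L)
        stop("transcript '", tid, "' mixes strands")
      if (length(unique(ttab$chrom)) != 1L)
        stop("transcript '", tid, "' spans multiple chromosomes")
      txs[[tid]] <- new_transcript(
        tid, gid, ttab$chrom[1L], ttab$strand[1L],
        ttab[, c("start", "end")],
        attributes = attr_by_tx[[tid]])
    }
    genes[[gid]] <- new_gene_model(gid, txs)
  }
  unname(genes[sort(names(genes))])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write gene models as GTF
#'
#' Emits one `exon` line per exon in GTF attribute style (`key "value";`),
#' converting back to 1-based inclusive coordinates. Output is
#' deterministic: genes and transcripts in id order, exons in genomic order.
#'
#' @param genes List of `gene_model` objects (or a single one).
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "exontype") {
  if (inherits(genes, "gene_model"))
    genes <- list(genes)
  genes <- genes[order(vapply(genes, `[[`, "", "gene_id"))]
  out <- character(0)
  for (g in genes) {
    for (tid in sort(names(g$transcripts))) {
      tx <- g$transcripts[[tid]]
      attrs <- tx$attributes
      # guarantee the two mandatory identifiers lead the field
      attrs <- c(c(gene_id = g$gene_id, transcript_id = tid),
                 attrs[!names(attrs) %in% c("gene_id", "transcript_id")])
      af <- format_attributes_gtf(attrs)
      out <- c(out, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                            tx$chrom, source, tx$exons$start + 1L,
                            tx$exons$end, tx$strand, af))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a genome FASTA into a sequence store
#'
#' Sequences are case-folded to uppercase and restricted to the
#' `{A,C,G,T,N}` alphabet; any other character is an error naming the
#' offending character. Duplicate sequence names are an error.
#'
#' @param path FASTA file.
#' @return Named character vector (class `genome_store`) mapping sequence
#'   name (first whitespace-delimited word of the header) to sequence.
#' @export
read_genome <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate sequence name: ", nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(set))
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(bad))) {
    j <- which(nzchar(bad))[1L]
    stop("non-nucleotide character '", substr(bad[j], 1L, 1L),
         "' in sequence '", nm[j], "'")
  }
  names(seqs) <- nm
  structure(seqs, class = "genome_store")
}

#' Write a sequence store as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write classification records as a BED-like file
#'
#' Eight tab-separated columns: chrom, start (0-based), end (half-open),
#' name (`gene_id:feature_index`), label, strand, supporting transcript ids
#' (comma-joined, sorted), original attributes (semicolon-joined
#' `key=value`). Records are ordered by (chrom, start, end, label). An empty
#' record set yields a header comment only.
#'
#' @param records `data.frame` as produced by [annotate_exons()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed_like <- function(records, path) {
  header <- "#chrom\tstart\tend\tname\tlabel\tstrand\ttranscripts\tattributes"
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  records <- records[order(records$chrom, records$start, records$end,
                           records$label), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
                   records$chrom, records$start, records$end, records$name,
                   records$label, records$strand, records$transcripts,
                   records$attributes)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED-like file written by [write_bed_like()]
#'
#' @param path File path.
#' @return `data.frame` with the eight documented columns.
#' @export
read_bed_like <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      label = character(0), strand = character(0),
                      transcripts = character(0), attributes = character(0)))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = f[, 1L], start = as.integer(f[, 2L]),
             end = as.integer(f[, 3L]), name = f[, 4L], label = f[, 5L],
             strand = f[, 6L], transcripts = f[, 7L], attributes = f[, 8L])
}
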