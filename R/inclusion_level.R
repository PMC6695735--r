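#' @title Exon inclusion levels from junction counts
#' @description An alternative exon's inclusion level (PSI) is the
#'   fraction of the gene's transcripts that include the exon, estimated
#'   from reads supporting its splice junctions: the two inclusion
#'   junctions (upstream exon -> target, target -> downstream exon) and
#'   the exclusion (skip) junction (upstream -> downstream). Estimates are
#'   classed into major (PSI at or above the cutoff) and minor isoforms.
#' @name inclusion_level
NULL

#' Read a splice-junction count table
#'
#' Tab-separated columns: chrom, intron start, intron end, strand, read
#' count. The `simple` dialect is 0-based half-open; the `sj_tab` dialect
#' (STAR-style) is 1-based inclusive and converted on read. Rows sharing a
#' key have their counts summed.
#'
#' @param path TSV file (optionally with `#` comment lines).
#' @param dialect `"simple"` or `"sj_tab"`.
#' @return `data.frame` keyed by (`chrom`, `start`, `end`, `strand`) with
#'   integer `count`.
#' @export
read_junctions <- function(path, dialect = c("simple", "sj_tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("junction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      count = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 0L) < 5L)
  if (length(bad))
    stop("junction line ", bad[1L], ": expected 5 tab-separated columns")
  tab <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                    start = as.integer(vapply(f, `[[`, "", 2L)),
                    end = as.integer(vapply(f, `[[`, "", 3L)),
                    strand = vapply(f, `[[`, "", 4L),
                    count = suppressWarnings(
                      as.integer(vapply(f, `[[`, "", 5L))))
  if (any(is.na(tab$start)) || any(is.na(tab$end)) || any(is.na(tab$count)))
    stop("junction table has non-numeric coordinates or counts")
  if (any(tab$count < 0L))
    stop("negative junction count: ", min(tab$count))
  if (any(!tab$strand %in% c("+", "-")))
    stop("bad strand symbol '",
         tab$strand[!tab$strand %in% c("+", "-")][1L], "'")
  if (dialect == "sj_tab")
    tab$start <- tab$start - 1L
  key <- paste(tab$chrom, tab$start, tab$end, tab$strand, sep = "\r")
  agg <- tapply(tab$count, key, sum)
  first <- tab[!duplicated(key), c("chrom", "start", "end", "strand")]
  first$count <- as.integer(agg[paste(first$chrom, first$start, first$end,
                                      first$strand, sep = "\r")])
  first <- first[order(first$chrom, first$start, first$end, first$strand), ,
                 drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Compute PSI from junction counts of one cassette exon
#'
#' Inclusion support is the mean of the two inclusion-junction counts (so
#' inclusion and exclusion are on the same per-event scale; `"min"` and
#' `"sum"` are available alternatives), and
#' `psi = inclusion / (inclusion + exclusion)`. A zero denominator yields a
#' missing estimate with class `undetermined`.
#'
#' @param inclusion_upstream,inclusion_downstream,exclusion Non-negative
#'   integer read counts.
#' @param denominator Rule combining the two inclusion junctions:
#'   `"mean"` (default), `"min"`, or `"sum"`.
#' @param major_cutoff PSI at or above which the exon is called the major
#'   isoform (default 0.5, the symmetric choice).
#' @return List with `psi` (in `[0, 1]` or `NA`), `n_effective` (the
#'   denominator used), `isoform_class` (`"major"`, `"minor"`,
#'   `"undetermined"`).
#' @export
compute_psi <- function(inclusion_upstream, inclusion_downstream, exclusion,
                        denominator = c("mean", "min", "sum"),
                        major_cutoff = 0.5) {
  denominator <- match.arg(denominator)
  counts <- c(inclusion_upstream, inclusion_downstream, exclusion)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("junction counts must be non-negative integers")
  inclusion <- switch(denominator,
                      mean = (inclusion_upstream + inclusion_downstream) / 2,
                      min = min(inclusion_upstream, inclusion_downstream),
                      sum = inclusion_upstream + inclusion_downstream)
  n_eff <- inclusion + exclusion
  if (n_eff == 0)
    return(list(psi = NA_real_, n_effective = 0,
                isoform_class = "undetermined"))
  psi <- inclusion / n_eff
  list(psi = psi, n_effective = n_eff,
       isoform_class = if (psi >= major_cutoff) "major" else "minor")
}

#' PSI estimates for the alternative cassette exons of a gene
#'
#' For each `AE_CASSETTE` exon-coordinate unit, the three junction keys are
#' derived from the reference isoform's intron chain: the upstream intron,
#' the downstream intron, and their fusion (skip junction). Junctions
#' absent from the table count as zero reads; an exon with no matching key
#' at all (including cassette exons absent from the reference isoform) gets
#' a missing estimate.
#'
#' @param gene A `gene_model`.
#' @param junctions Junction table from [read_junctions()] (or equivalent
#'   `data.frame`).
#' @param exon_calls Optional precomputed [classify_exons_intact()] output.
#' @param denominator,major_cutoff Passed to [compute_psi()].
#' @return `data.frame` with one row per cassette exon: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `label`, `inclusion_upstream`,
#'   `inclusion_downstream`, `exclusion`, `psi`, `n_effective`,
#'   `isoform_class`.
#' @export
psi_for_gene <- function(gene, junctions,
                         exon_calls = classify_exons_intact(gene),
                         denominator = "mean", major_cutoff = 0.5) {
  ref <- gene$transcripts[[select_reference_isoform(gene)]]
  rex <- ref$exons
  cass <- exon_calls[exon_calls$label == "AE_CASSETTE", , drop = FALSE]
  lookup <- function(s, e) {
    hit <- junctions$chrom == gene$chrom & junctions$start == s &
      junctions$end == e & junctions$strand == gene$strand
    if (any(hit)) sum(junctions$count[hit]) else NA_integer_
  }
  rows <- lapply(seq_len(nrow(cass)), function(i) {
    s <- cass$start[i]
    e <- cass$end[i]
    k <- which(rex$start == s & rex$end == e)
    base <- data.frame(
      gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
      start = s, end = e, label = cass$label[i],
      inclusion_upstream = NA_integer_, inclusion_downstream = NA_integer_,
      exclusion = NA_integer_, psi = NA_real_, n_effective = 0,
      isoform_class = "undetermined")
    if (length(k) != 1L || k == 1L || k == nrow(rex))
      return(base)  # not an internal reference exon: no junction triplet
    up <- lookup(rex$end[k - 1L], s)        # upstream exon -> target
    dn <- lookup(e, rex$start[k + 1L])      # target -> downstream exon
    skip <- lookup(rex$end[k - 1L], rex$start[k + 1L])
    if (is.na(up) && is.na(dn) && is.na(skip))
      return(base)
    up <- if (is.na(up)) 0L else up
    dn <- if (is.na(dn)) 0L else dn
    skip <- if (is.na(skip)) 0L else skip
    # orient inclusion junctions in transcription direction
    if (gene$strand == "-") {
      tmp <- up; up <- dn; dn <- tmp
    }
    est <- compute_psi(up, dn, skip, denominator = denominator,
                       major_cutoff = major_cutoff)
    base$inclusion_upstream <- up
    base$inclusion_downstream <- dn
    base$exclusion <- skip
    base$psi <- est$psi
    base$n_effective <- est$n_effective
    base$isoform_class <- est$isoform_class
    base
  })
  out <- do.call(rbind, c(list(data.frame(
    gene_id = character(0), chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0), label = character(0),
    inclusion_upstream = integer(0), inclusion_downstream = integer(0),
    exclusion = integer(0), psi = numeric(0), n_effective = numeric(0),
    isoform_class = character(0))), rows))
  rownames(out) <- NULL
  out
}
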