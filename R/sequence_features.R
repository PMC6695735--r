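#' @title Splicing sequence features
#' @description Position-weight-matrix splice-site strength, branch-point
#'   and polypyrimidine-tract detection, splicing-regulatory-element (SRE)
#'   k-mer scanning, and exon-intron architecture features.
#'
#'   Window conventions: the donor (5' splice site) window is 9 nt,
#'   spanning the exon/intron boundary with 3 exonic (-3..-1) and 6
#'   intronic (+1..+6) positions; canonical donor introns start `GT`
#'   (>98%) or `GC` (<1%). The acceptor (3' splice site) window is 23 nt:
#'   the last 20 intronic positions (-20..-1, ending in the canonical `AG`)
#'   plus the first 3 exonic positions (+1..+3). The acceptor-side window
#'   length is a package convention (only the donor window is a stated
#'   constant); it covers the PPT and AG.
#' @name sequence_features
NULL

DONOR_WINDOW_EXONIC <- 3L
DONOR_WINDOW_INTRONIC <- 6L
ACCEPTOR_WINDOW_INTRONIC <- 20L
ACCEPTOR_WINDOW_EXONIC <- 3L
DONOR_CONSENSUS <- "CAGGTAAGT"
ACCEPTOR_CONSENSUS <- "TTTTTTTTTTTTTTTTTCAGGCT"
CANONICAL_DONOR_DINUCLEOTIDES <- c("GT", "GC")
ACCEPTOR_DINUCLEOTIDE <- "AG"
DNA_BASES <- c("A", "C", "G", "T")

donor_window_length <- function() DONOR_WINDOW_EXONIC + DONOR_WINDOW_INTRONIC
acceptor_window_length <- function()
  ACCEPTOR_WINDOW_INTRONIC + ACCEPTOR_WINDOW_EXONIC

#' Extract a splice-site window from the genome
#'
#' Returns the strand-oriented window across an internal exon boundary:
#' 9 nt for `side = "donor"` (3 exonic + 6 intronic in transcription
#' direction), 23 nt for `side = "acceptor"` (20 intronic + 3 exonic).
#' Minus-strand windows are reverse-complemented so the returned string
#' always reads in transcription direction.
#'
#' @param genome A `genome_store` from [read_genome()].
#' @param tx An `exon_transcript`.
#' @param exon_index Exon ordinal in *transcription* order (1 = first
#'   transcribed exon).
#' @param side `"donor"` or `"acceptor"`.
#' @return Nucleotide string (may contain `N`).
#' @export
extract_site_window <- function(genome, tx, exon_index,
                                side = c("donor", "acceptor")) {
  side <- match.arg(side)
  n <- nrow(tx$exons)
  if (exon_index < 1L || exon_index > n)
    stop("exon_index ", exon_index, " out of range (", n, " exons)")
  if (side == "donor" && exon_index == n)
    stop("no splice site: last exon has no donor")
  if (side == "acceptor" && exon_index == 1L)
    stop("no splice site: first exon has no acceptor")
  # map transcription order -> genomic order
  g_idx <- if (tx$strand == "+") exon_index else n - exon_index + 1L
  ex <- tx$exons
  if (tx$strand == "+") {
    if (side == "donor") {
      e <- ex$end[g_idx]
      genome_slice(genome, tx$chrom, e - DONOR_WINDOW_EXONIC,
                   e + DONOR_WINDOW_INTRONIC)
    } else {
      s <- ex$start[g_idx]
      genome_slice(genome, tx$chrom, s - ACCEPTOR_WINDOW_INTRONIC,
                   s + ACCEPTOR_WINDOW_EXONIC)
    }
  } else {
    if (side == "donor") {
      s <- ex$start[g_idx]
      revcomp(genome_slice(genome, tx$chrom, s - DONOR_WINDOW_INTRONIC,
                           s + DONOR_WINDOW_EXONIC))
    } else {
      e <- ex$end[g_idx]
      revcomp(genome_slice(genome, tx$chrom, e - ACCEPTOR_WINDOW_EXONIC,
                           e + ACCEPTOR_WINDOW_INTRONIC))
    }
  }
}

#' Train a splice-site position weight matrix
#'
#' Per-position nucleotide frequencies with Laplace-style pseudocount:
#' `f[i, b] = (count + alpha) / (n + 4 * alpha)`. The default background is
#' uniform (0.25 per base).
#'
#' @param windows Character vector of equal-length nucleotide strings.
#' @param site_kind `"donor"` or `"acceptor"`; the window length must match
#'   the corresponding convention (9 or 23 nt).
#' @param alpha Pseudocount (default 1; avoids -Inf log-odds on held-out
#'   windows).
#' @param background Named numeric of base probabilities summing to 1.
#' @return Object of class `splice_pwm` with elements `site_kind`, `freq`
#'   (4 x L matrix, rows A/C/G/T), `alpha`, `background`, `n`.
#' @export
train_pwm <- function(windows, site_kind = c("donor", "acceptor"),
                      alpha = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  site_kind <- match.arg(site_kind)
  if (length(windows) == 0L)
    stop("no training windows")
  windows <- toupper(windows)
  L <- unique(nchar(windows))
  if (length(L) != 1L)
    stop("training windows differ in length")
  expected <- if (site_kind == "donor") donor_window_length() else
    acceptor_window_length()
  if (L != expected)
    stop(site_kind, " windows must be ", expected, " nt, got ", L)
  if (alpha < 0)
    stop("pseudocount must be >= 0")
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-8)
    stop("background must assign probabilities to A,C,G,T summing to 1")
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  n_eff <- integer(L)
  freq <- matrix(0, nrow = 4L, ncol = L,
                 dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(L)) {
    col <- mat[, i]
    col <- col[col %in% DNA_BASES]  # N positions carry no information
    n_eff[i] <- length(col)
    counts <- table(factor(col, levels = DNA_BASES))
    freq[, i] <- (as.numeric(counts) + alpha) /
      (length(col) + 4 * alpha)
  }
  if (any(n_eff == 0L) && alpha == 0)
    stop("a position has no informative bases and alpha = 0")
  structure(list(site_kind = site_kind, freq = freq, alpha = alpha,
                 background = background, n = length(windows)),
            class = "splice_pwm")
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("<splice_pwm %s, %d positions, n = %d, alpha = %g>\n",
              x$site_kind, ncol(x$freq), x$n, x$alpha))
  invisible(x)
}

#' Score a splice-site window against a PWM
#'
#' Log-odds splicing strength in bits:
#' `score = sum_i log2(f[i, w_i] / q[w_i])`. Windows containing `N` return
#' `NA` (the missing-value marker); characters outside `{A,C,G,T,N}` are an
#' error.
#'
#' @param pwm A `splice_pwm`.
#' @param window Nucleotide string whose length matches the PWM.
#' @return Numeric score in bits, or `NA_real_`.
#' @export
score_site <- function(pwm, window) {
  window <- toupper(window)
  L <- ncol(pwm$freq)
  if (nchar(window) != L)
    stop("window length ", nchar(window), " does not match PWM (", L, ")")
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c(DNA_BASES, "N")))
    stop("invalid character '", setdiff(chars, c(DNA_BASES, "N"))[1L],
         "' in window")
  if (any(chars == "N"))
    return(NA_real_)
  rows <- match(chars, DNA_BASES)
  sum(log2(pwm$freq[cbind(rows, seq_len(L))] / pwm$background[chars]))
}

#' Consensus (argmax) window of a PWM
#'
#' @param pwm A `splice_pwm`.
#' @return The per-position argmax string, which attains the supremum
#'   score. Ties resolve to the alphabetically first base.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2L, which.max)], collapse = "")
}

#' Persist a PWM as a tab-separated matrix file
#'
#' @param pwm A `splice_pwm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#site_kind\t%s", pwm$site_kind), con)
  writeLines(sprintf("#alpha\t%g", pwm$alpha), con)
  writeLines(sprintf("#n\t%d", pwm$n), con)
  writeLines(sprintf("#background\t%s",
                     paste(sprintf("%s=%.10g", DNA_BASES,
                                   pwm$background[DNA_BASES]),
                           collapse = ",")), con)
  writeLines(paste(c("base", paste0("p", seq_len(ncol(pwm$freq)))),
                   collapse = "\t"), con)
  for (b in DNA_BASES)
    writeLines(paste(c(b, sprintf("%.10g", pwm$freq[b, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#'
#' @param path File path.
#' @return A `splice_pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "\t"))]
    strsplit(hit[1L], "\t", fixed = TRUE)[[1L]][2L]
  }
  bg_parts <- strsplit(strsplit(get_meta("background"), ",")[[1L]], "=")
  background <- as.numeric(vapply(bg_parts, `[[`, "", 2L))
  names(background) <- vapply(bg_parts, `[[`, "", 1L)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  freq <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(freq) <- vapply(rows, `[[`, "", 1L)
  freq <- freq[DNA_BASES, , drop = FALSE]
  structure(list(site_kind = get_meta("site_kind"), freq = freq,
                 alpha = as.numeric(get_meta("alpha")),
                 background = background,
                 n = as.integer(get_meta("n"))),
            class = "splice_pwm")
}

#' Branch-point search configuration
#'
#' The branch point is a degenerate intronic motif, consensus `YUNAY`
#' (DNA: `Y T N A Y`, Y = C/T), bound during lariat formation. Most branch
#' points sit 14-50 nt upstream of the 3' splice site; distal ones occur up
#' to 350 nt upstream, which bounds the search.
#'
#' @param min_distance Closest motif start considered, in nt upstream of
#'   the intron's 3' end (default 14).
#' @param typical_max Distance beyond which a candidate is flagged distal
#'   (default 50).
#' @param hard_max Search bound (default 350).
#' @return List of class `bp_config`.
#' @export
bp_config <- function(min_distance = 14L, typical_max = 50L,
                      hard_max = 350L) {
  stopifnot(min_distance < typical_max, typical_max <= hard_max)
  structure(list(min_distance = as.integer(min_distance),
                 typical_max = as.integer(typical_max),
                 hard_max = as.integer(hard_max)),
            class = "bp_config")
}

matches_yunay <- function(chars) {
  length(chars) == 5L &&
    chars[1L] %in% c("C", "T") && chars[2L] == "T" &&
    chars[3L] %in% DNA_BASES && chars[4L] == "A" &&
    chars[5L] %in% c("C", "T")
}

#' Find the branch-point candidate of an intron
#'
#' Scans motif start positions from `min_distance` to `hard_max` nt
#' upstream of the intron's 3' end (distance counts the motif's first base,
#' inclusive) and returns the `YUNAY` match closest to the 3' splice site,
#' or `NULL` if none. `N` never matches.
#'
#' @param intron_seq Intron sequence in transcription direction (5'->3').
#' @param config A [bp_config()].
#' @return `NULL`, or a list with `distance` (nt upstream of the 3' end),
#'   `start` (0-based offset within the intron), `motif` (matched 5-mer),
#'   and `distal` (`TRUE` when beyond `typical_max`).
#' @export
find_branch_point <- function(intron_seq, config = bp_config()) {
  seq <- toupper(intron_seq)
  L <- nchar(seq)
  if (L < config$min_distance + 0L)
    return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (d in config$min_distance:min(config$hard_max, L)) {
    p <- L - d + 1L  # 1-based motif start
    if (p + 4L > L)
      next
    if (matches_yunay(chars[p:(p + 4L)]))
      return(list(distance = d, start = p - 1L,
                  motif = substr(seq, p, p + 4L),
                  distal = d > config$typical_max))
  }
  NULL
}

#' Polypyrimidine-tract search configuration
#'
#' The PPT is a ~20-nt pyrimidine-rich motif generally separated from the
#' terminal `AG` dinucleotide by about 2 nt. The numeric thresholds
#' (fraction, minimum length, search span) are package conventions.
#'
#' @param min_pyrimidine_fraction Minimum C/T fraction of a reported run
#'   (default 0.7).
#' @param min_length Minimum run length (default 10).
#' @param search_span Search window at the intron's 3' end, nt (default 50).
#' @param gap_to_ag Gap between the tract and the terminal `AG` (default 2).
#' @return List of class `ppt_config`.
#' @export
ppt_config <- function(min_pyrimidine_fraction = 0.7, min_length = 10L,
                       search_span = 50L, gap_to_ag = 2L) {
  stopifnot(min_pyrimidine_fraction >= 0, min_pyrimidine_fraction <= 1,
            min_length >= 1L, search_span > min_length, gap_to_ag >= 0L)
  structure(list(min_pyrimidine_fraction = min_pyrimidine_fraction,
                 min_length = as.integer(min_length),
                 search_span = as.integer(search_span),
                 gap_to_ag = as.integer(gap_to_ag)),
            class = "ppt_config")
}

#' Find the polypyrimidine tract of an intron
#'
#' Within the last `search_span` nt of the intron, excluding the terminal
#' `AG` dinucleotide and the `gap_to_ag` spacer, returns the longest
#' contiguous run with pyrimidine (C/T) fraction at or above the threshold
#' and length at or above `min_length`; length ties break toward the 3'
#' splice site.
#'
#' @param intron_seq Intron sequence in transcription direction.
#' @param config A [ppt_config()].
#' @return `NULL`, or a list with `start` (0-based offset within the
#'   intron), `length`, and `pyrimidine_fraction`.
#' @export
find_ppt <- function(intron_seq, config = ppt_config()) {
  seq <- toupper(intron_seq)
  L <- nchar(seq)
  if (L < 10L)
    return(NULL)
  lo <- max(1L, L - config$search_span + 1L)
  hi <- L - 2L - config$gap_to_ag
  if (hi - lo + 1L < config$min_length)
    return(NULL)
  chars <- strsplit(substr(seq, lo, hi), "", fixed = TRUE)[[1L]]
  is_pyr <- chars %in% c("C", "T")
  w <- length(is_pyr)
  cum <- c(0L, cumsum(is_pyr))
  best <- NULL
  for (len in seq(w, config$min_length)) {
    for (s in seq(w - len + 1L, 1L)) {   # 3'-most start first
      frac <- (cum[s + len] - cum[s]) / len
      if (frac >= config$min_pyrimidine_fraction) {
        best <- list(start = lo + s - 2L,  # 0-based within intron
                     length = len, pyrimidine_fraction = frac)
        break
      }
    }
    if (!is.null(best))
      break
  }
  best
}

#' Default splicing-regulatory-element motif set
#'
#' The six SRE cluster motifs enriched near alternative cassette exons,
#' stored as DNA (U -> T): `TCTCT`, `TGCATG`, `TGCT`, `TGTGT`, `TTTT`,
#' `AGGG`.
#'
#' @return Named character vector of DNA motifs.
#' @export
default_sre_motifs <- function() {
  c(UCUCU = "TCTCT", UGCAUG = "TGCATG", UGCU = "TGCT",
    UGUGU = "TGTGT", UUUU = "TTTT", AGGG = "AGGG")
}

#' Scan a sequence for SRE motifs
#'
#' Exact matching with overlaps allowed (a run of five `T`s contains two
#' `TTTT` matches). Motifs given as RNA are converted to DNA. The sequence
#' is expected strand-oriented; reverse-complement minus-strand sequence
#' before calling.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (RNA accepted).
#' @param motifs Character vector of motifs (default
#'   [default_sre_motifs()]); names are kept as motif labels.
#' @param class Optional SRE class annotation recycled across motifs
#'   (e.g. `"ESE"`, `"ESS"`, `"ISE"`, `"ISS"`).
#' @return `data.frame` with one row per motif: `motif` (label), `kmer`
#'   (DNA), `count`, `density_per_100nt`, and a list column `positions`
#'   (0-based match offsets).
#' @export
scan_sre <- function(seq, motifs = default_sre_motifs(), class = NA_character_) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  if (length(motifs) == 0L)
    return(data.frame(motif = character(0), kmer = character(0),
                      class = character(0), count = integer(0),
                      density_per_100nt = numeric(0)))
  kmers <- toupper(chartr("U", "T", motifs))
  labels <- if (is.null(names(motifs))) kmers else names(motifs)
  L <- nchar(seq)
  pos <- lapply(kmers, function(k) {
    if (L < nchar(k))
      return(integer(0))
    m <- Biostrings::matchPattern(k, Biostrings::DNAString(seq))
    as.integer(Biostrings::start(m)) - 1L
  })
  res <- data.frame(motif = labels, kmer = kmers,
                    class = rep_len(class, length(kmers)),
                    count = vapply(pos, length, 0L),
                    density_per_100nt =
                      vapply(pos, length, 0L) / max(L, 1L) * 100)
  res$positions <- pos
  rownames(res) <- NULL
  res
}

#' Exon-intron architecture features
#'
#' One row per exon-coordinate unit of the gene (see
#' [classify_exons_intact()]): exon length; flanking intron lengths taken
#' from the reference isoform's intron chain (upstream/downstream in
#' transcription direction; `NA` where the reference has no intron on that
#' side); intron-to-exon ratio (mean of the defined flanking intron
#' lengths over the exon length); reading-frame symmetry (length divisible
#' by 3); and, when a genome is supplied, exon GC content and boundary GC
#' over fixed windows straddling each junction.
#'
#' @param gene A `gene_model`.
#' @param genome Optional `genome_store`; GC columns are `NA` without it.
#' @param boundary_window Half-width, nt, of the boundary-GC window on each
#'   side of the junction (default 25; a package convention).
#' @param include_end_variation Passed to [classify_exons_intact()].
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `label`, `exon_length`, `upstream_intron_length`,
#'   `downstream_intron_length`, `intron_to_exon_ratio`, `symmetric`,
#'   `exon_gc`, `upstream_boundary_gc`, `downstream_boundary_gc`.
#' @export
architecture <- function(gene, genome = NULL, boundary_window = 25L,
                         include_end_variation = FALSE) {
  calls <- classify_exons_intact(gene, include_end_variation)
  ref <- gene$transcripts[[select_reference_isoform(gene)]]
  ri <- introns(ref)
  strand <- gene$strand
  n <- nrow(calls)
  res <- calls[, c("gene_id", "chrom", "strand", "start", "end", "label")]
  res$exon_length <- calls$end - calls$start
  left_len <- right_len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lefts <- which(ri$end <= calls$start[i])
    rights <- which(ri$start >= calls$end[i])
    if (length(lefts))
      left_len[i] <- ri$end[max(lefts)] - ri$start[max(lefts)]
    if (length(rights))
      right_len[i] <- ri$end[min(rights)] - ri$start[min(rights)]
  }
  if (strand == "+") {
    res$upstream_intron_length <- left_len
    res$downstream_intron_length <- right_len
  } else {
    res$upstream_intron_length <- right_len
    res$downstream_intron_length <- left_len
  }
  res$intron_to_exon_ratio <- vapply(seq_len(n), function(i) {
    fl <- c(res$upstream_intron_length[i], res$downstream_intron_length[i])
    fl <- fl[!is.na(fl)]
    if (length(fl) == 0L) NA_real_ else mean(fl) / res$exon_length[i]
  }, 0)
  res$symmetric <- res$exon_length %% 3L == 0L
  res$exon_gc <- NA_real_
  res$upstream_boundary_gc <- NA_real_
  res$downstream_boundary_gc <- NA_real_
  if (!is.null(genome)) {
    w <- as.integer(boundary_window)
    chrom_len <- nchar(genome[[gene$chrom]])
    bgc <- function(pos) {
      if (pos - w < 0L || pos + w > chrom_len)
        return(NA_real_)
      gc_content(genome_slice(genome, gene$chrom, pos - w, pos + w))
    }
    for (i in seq_len(n)) {
      res$exon_gc[i] <- gc_content(
        genome_slice(genome, gene$chrom, calls$start[i], calls$end[i]))
      left_gc <- bgc(calls$start[i])
      right_gc <- bgc(calls$end[i])
      if (strand == "+") {
        res$upstream_boundary_gc[i] <- left_gc
        res$downstream_boundary_gc[i] <- right_gc
      } else {
        res$upstream_boundary_gc[i] <- right_gc
        res$downstream_boundary_gc[i] <- left_gc
      }
    }
  }
  res
}
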