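#' @title Exon classification and event detection
#' @description Implements the two exon-classification schemes (intact
#'   exon-coordinate units; per-base constitutive/alternative regions) and
#'   the alternative-splicing event taxonomy (exon skipping, alternative
#'   3'/5' splice site, intron retention, exonic intron) relative to a
#'   reference isoform.
#'
#'   Boundary vocabulary is strand-aware and follows transcription
#'   direction: the donor (5' splice site) side of an exon is its genomic
#'   end on `+` and its genomic start on `-`; the acceptor (3' splice site)
#'   side is the opposite.
#' @name exon_classify
NULL

EXON_LABELS <- c("CE", "AE_CASSETTE", "AE_ALT3SS", "AE_ALT5SS",
                 "AE_ALT_BOTH", "AE_IR_MERGED")
EVENT_TYPES <- c("ES", "A3SS", "A5SS", "IR", "EXONIC_INTRON")

# donor/acceptor genomic coordinate of an intron
intron_donor <- function(start, end, strand) if (strand == "+") start else end
intron_acceptor <- function(start, end, strand) if (strand == "+") end else start

#' Select the reference isoform
#'
#' The reference isoform `i0` is the transcript with the maximum exon
#' count; ties are broken by the longest summed exon length, then by the
#' lexicographically smallest transcript id, so selection is deterministic.
#'
#' @param gene A `gene_model`.
#' @return The reference `transcript_id`.
#' @export
select_reference_isoform <- function(gene) {
  txs <- gene$transcripts
  n_ex <- vapply(txs, function(t) nrow(t$exons), 0L)
  len <- vapply(txs, function(t) sum(t$exons$end - t$exons$start), 0L)
  ids <- names(txs)
  ord <- order(-n_ex, -len, ids)
  ids[ord[1L]]
}

empty_events <- function() {
  data.frame(gene_id = character(0), event_type = character(0),
             ref_id = character(0), alt_id = character(0),
             chrom = character(0), strand = character(0),
             start = integer(0), end = integer(0))
}

#' Detect alternative-splicing events between two isoforms
#'
#' Compares an alternative isoform against a reference by pure interval
#' relations:
#' * **ES** — an exon of `ref` lies entirely within one intron of `alt`.
#' * **A3SS** — an intron of `alt` shares its donor boundary with an intron
#'   of `ref` but differs at the acceptor boundary.
#' * **A5SS** — shares the acceptor boundary, differs at the donor.
#' * **IR** — an exon of `alt` exactly spans consecutive exons of `ref`
#'   plus the intervening intron(s); one event per retained intron.
#' * **EXONIC_INTRON** — an intron of `alt` lies strictly inside a single
#'   exon of `ref` (both boundaries internal).
#'
#' An intron pair is not reported as A3SS/A5SS when either intron fully
#' contains a complete exon of the other transcript: that boundary
#' difference is a consequence of exon skipping/inclusion, not competing
#' splice-site choice. Multiple events per isoform pair are allowed.
#'
#' The reported interval is the skipped exon (ES), the region between the
#' two competing boundaries (A3SS/A5SS), the retained intron (IR), or the
#' excised internal region (EXONIC_INTRON).
#'
#' @param ref,alt `exon_transcript` objects from the same gene and strand.
#' @return `data.frame` with columns `gene_id`, `event_type`, `ref_id`,
#'   `alt_id`, `chrom`, `strand`, `start`, `end`; zero rows when the
#'   isoforms are splice-identical.
#' @export
detect_events <- function(ref, alt) {
  if (ref$gene_id != alt$gene_id)
    stop("isoforms belong to different genes: ", ref$gene_id, " vs ",
         alt$gene_id)
  if (ref$chrom != alt$chrom || ref$strand != alt$strand)
    stop("isoforms differ in chromosome or strand")
  strand <- ref$strand
  rex <- ref$exons
  aex <- alt$exons
  ri <- introns(ref)
  ai <- introns(alt)
  ev <- list()
  add <- function(type, s, e)
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = ref$gene_id, event_type = type, ref_id = ref$transcript_id,
      alt_id = alt$transcript_id, chrom = ref$chrom, strand = strand,
      start = as.integer(s), end = as.integer(e))

  # ES: ref exon entirely within an alt intron
  for (k in seq_len(nrow(rex)))
    for (j in seq_len(nrow(ai)))
      if (ai$start[j] <= rex$start[k] && rex$end[k] <= ai$end[j])
        add("ES", rex$start[k], rex$end[k])

  # IR: alt exon = exact span of >=2 consecutive ref exons; one event per
  # retained ref intron
  for (k in seq_len(nrow(aex))) {
    m1 <- which(rex$start == aex$start[k])
    m2 <- which(rex$end == aex$end[k])
    if (length(m1) == 1L && length(m2) == 1L && m2 > m1)
      for (j in m1:(m2 - 1L))
        add("IR", ri$start[j], ri$end[j])
  }

  # EXONIC_INTRON: alt intron strictly inside a single ref exon
  for (j in seq_len(nrow(ai)))
    for (k in seq_len(nrow(rex)))
      if (rex$start[k] < ai$start[j] && ai$end[j] < rex$end[k])
        add("EXONIC_INTRON", ai$start[j], ai$end[j])

  # A3SS / A5SS over intron pairs, with the skipping exclusion
  contains_complete_exon <- function(s, e, ex)
    any(s <= ex$start & ex$end <= e)
  for (j in seq_len(nrow(ai))) {
    if (contains_complete_exon(ai$start[j], ai$end[j], rex))
      next
    for (i in seq_len(nrow(ri))) {
      if (contains_complete_exon(ri$start[i], ri$end[i], aex))
        next
      don_r <- intron_donor(ri$start[i], ri$end[i], strand)
      don_a <- intron_donor(ai$start[j], ai$end[j], strand)
      acc_r <- intron_acceptor(ri$start[i], ri$end[i], strand)
      acc_a <- intron_acceptor(ai$start[j], ai$end[j], strand)
      if (don_r == don_a && acc_r != acc_a)
        add("A3SS", min(acc_r, acc_a), max(acc_r, acc_a))
      if (acc_r == acc_a && don_r != don_a)
        add("A5SS", min(don_r, don_a), max(don_r, don_a))
    }
  }

  if (length(ev) == 0L)
    return(empty_events())
  out <- unique(do.call(rbind, ev))
  out <- out[order(out$start, out$end, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect events for a whole gene against its reference isoform
#'
#' Union of [detect_events()] over all isoforms versus the automatically
#' selected reference `i0`; set `all_pairs = TRUE` for an all-vs-all
#' comparison instead.
#'
#' @param gene A `gene_model`.
#' @param all_pairs Compare every ordered isoform pair instead of `i0`
#'   versus the rest.
#' @return Event `data.frame` (see [detect_events()]).
#' @export
gene_events <- function(gene, all_pairs = FALSE) {
  ids <- names(gene$transcripts)
  pairs <- if (all_pairs) {
    subset(expand.grid(ref = ids, alt = ids, stringsAsFactors = FALSE),
           ref != alt)
  } else {
    ref <- select_reference_isoform(gene)
    alts <- setdiff(ids, ref)
    data.frame(ref = rep(ref, length(alts)), alt = alts)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i)
    detect_events(gene$transcripts[[pairs$ref[i]]],
                  gene$transcripts[[pairs$alt[i]]]))
  out <- do.call(rbind, c(list(empty_events()), out))
  rownames(out) <- NULL
  out
}

# TRUE when tuple (s, e) sits as an exact exon in transcript tx
has_exact_exon <- function(tx, s, e)
  any(tx$exons$start == s & tx$exons$end == e)

#' Classify intact exon-coordinate units
#'
#' The classification units are the distinct exon coordinate tuples of the
#' gene (scheme 1: every exon kept intact). Labels:
#' * `CE` — present verbatim in every transcript;
#' * `AE_CASSETTE` — lies entirely within an intron of at least one
#'   transcript (that transcript splices over it);
#' * `AE_ALT3SS` / `AE_ALT5SS` / `AE_ALT_BOTH` — the acceptor-side and/or
#'   donor-side boundary competes with a different splice site in another
#'   transcript (intron-anchored evidence, with the exon-skipping exclusion
#'   of [detect_events()]); the variable end(s) are recorded;
#' * `AE_IR_MERGED` — the unit spans two or more consecutive exons of
#'   another transcript plus the intervening intron(s) (a retained intron,
#'   or equivalently the intact form of an exonic intron).
#'
#' Exons whose only alternative partner is an IR-merged unit (the flanks of
#' a retained intron; the split forms of an exonic intron) carry no
#' intron-anchored evidence; they fall back to a direct exon-overlap
#' comparison to record which end varies.
#'
#' With `include_end_variation = FALSE` (default), variation only at the
#' transcription start (acceptor side of a transcript's first exon) or the
#' transcription end (donor side of its last exon) does not make an exon
#' alternative: such units are labelled `CE`, since the difference arises
#' at transcription initiation/termination, not splicing.
#'
#' @param gene A `gene_model`.
#' @param include_end_variation Treat TSS/TES variation as alternative.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `exon_index` (ordinal among distinct tuples in genomic order),
#'   `label`, `transcripts` (comma-joined sorted supporting ids),
#'   `variable_ends` (comma-joined subset of `acceptor_end`, `donor_end`).
#' @export
classify_exons_intact <- function(gene, include_end_variation = FALSE) {
  units <- exon_units(gene)
  txs <- gene$transcripts
  n_tx <- length(txs)
  strand <- gene$strand
  tx_intr <- lapply(txs, introns)

  # transcription-first/last exon index (genomic) per transcript
  tx_first <- vapply(txs, function(t)
    if (strand == "+") 1L else nrow(t$exons), 0L)
  tx_last <- vapply(txs, function(t)
    if (strand == "+") nrow(t$exons) else 1L, 0L)

  # IR-merged units: exact span of >=2 consecutive exons of some transcript
  is_merged <- function(s, e) any(vapply(txs, function(t) {
    m1 <- which(t$exons$start == s)
    m2 <- which(t$exons$end == e)
    length(m1) == 1L && length(m2) == 1L && m2 > m1
  }, TRUE))
  merged_units <- vapply(seq_len(nrow(units)), function(u)
    is_merged(units$start[u], units$end[u]), TRUE)
  # boundary abuts a merged exon: competing-site evidence from such a
  # boundary is retention, not splice-site choice, and is ignored
  boundary_is_merged <- function(t2, coord, side) {
    ex2 <- txs[[t2]]$exons
    k <- if (side == "start") which(ex2$start == coord) else
      which(ex2$end == coord)
    length(k) == 1L &&
      any(units$start == ex2$start[k] & units$end == ex2$end[k] &
            merged_units)
  }

  out <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    s <- units$start[u]
    e <- units$end[u]
    containing <- names(txs)[vapply(txs, has_exact_exon, TRUE, s, e)]
    all_have <- length(containing) == n_tx
    merged <- merged_units[u]

    cassette <- any(vapply(names(txs), function(tid) {
      it <- tx_intr[[tid]]
      any(it$start <= s & e <= it$end)
    }, TRUE))

    acc_varies <- FALSE
    don_varies <- FALSE
    for (t1 in containing) {
      ex1 <- txs[[t1]]$exons
      it1 <- tx_intr[[t1]]
      idx <- which(ex1$start == s & ex1$end == e)
      # upstream intron (acceptor side) / downstream intron (donor side)
      up <- if (strand == "+") which(it1$end == s) else which(it1$start == e)
      dn <- if (strand == "+") which(it1$start == e) else which(it1$end == s)
      for (t2 in setdiff(names(txs), t1)) {
        it2 <- tx_intr[[t2]]
        for (j in seq_len(nrow(it2))) {
          j_s <- it2$start[j]
          j_e <- it2$end[j]
          don_j <- intron_donor(j_s, j_e, strand)
          acc_j <- intron_acceptor(j_s, j_e, strand)
          skip_j <- any(j_s <= ex1$start & ex1$end <= j_e)
          if (length(up) == 1L) {
            i_s <- it1$start[up]
            i_e <- it1$end[up]
            skip_i <- any(i_s <= txs[[t2]]$exons$start &
                            txs[[t2]]$exons$end <= i_e)
            if (!skip_j && !skip_i &&
                intron_donor(i_s, i_e, strand) == don_j &&
                intron_acceptor(i_s, i_e, strand) != acc_j &&
                !boundary_is_merged(t2, acc_j,
                                    if (strand == "+") "start" else "end"))
              acc_varies <- TRUE
          }
          if (length(dn) == 1L) {
            i_s <- it1$start[dn]
            i_e <- it1$end[dn]
            skip_i <- any(i_s <= txs[[t2]]$exons$start &
                            txs[[t2]]$exons$end <= i_e)
            if (!skip_j && !skip_i &&
                intron_acceptor(i_s, i_e, strand) == acc_j &&
                intron_donor(i_s, i_e, strand) != don_j &&
                !boundary_is_merged(t2, don_j,
                                    if (strand == "+") "end" else "start"))
              don_varies <- TRUE
          }
        }
      }
    }

    label <- NA_character_
    if (all_have) {
      label <- "CE"
    } else if (merged) {
      label <- "AE_IR_MERGED"
    } else if (cassette) {
      label <- "AE_CASSETTE"
    } else if (acc_varies || don_varies) {
      label <- if (acc_varies && don_varies) "AE_ALT_BOTH"
      else if (acc_varies) "AE_ALT3SS" else "AE_ALT5SS"
    } else {
      # fallback: direct exon-overlap comparison (covers IR/exonic-intron
      # flanks and TSS/TES variation)
      for (t2 in setdiff(names(txs), containing)) {
        ex2 <- txs[[t2]]$exons
        for (k in seq_len(nrow(ex2))) {
          f_s <- ex2$start[k]
          f_e <- ex2$end[k]
          if (f_e <= s || e <= f_s)
            next
          acc_u <- if (strand == "+") s else e
          acc_f <- if (strand == "+") f_s else f_e
          don_u <- if (strand == "+") e else s
          don_f <- if (strand == "+") f_e else f_s
          # is the differing boundary a transcription start/end on both
          # sides rather than a splice site?
          u_first <- all(vapply(containing, function(t1) {
            i <- which(txs[[t1]]$exons$start == s &
                         txs[[t1]]$exons$end == e)
            i == tx_first[[t1]]
          }, TRUE))
          u_last <- all(vapply(containing, function(t1) {
            i <- which(txs[[t1]]$exons$start == s &
                         txs[[t1]]$exons$end == e)
            i == tx_last[[t1]]
          }, TRUE))
          f_first <- k == tx_first[[t2]]
          f_last <- k == tx_last[[t2]]
          if (acc_u != acc_f && don_u == don_f &&
              (include_end_variation || !(u_first && f_first)))
            acc_varies <- TRUE
          if (don_u != don_f && acc_u == acc_f &&
              (include_end_variation || !(u_last && f_last)))
            don_varies <- TRUE
          if (acc_u != acc_f && don_u != don_f &&
              (include_end_variation || !(u_first && f_first) ||
                 !(u_last && f_last))) {
            if (include_end_variation || !(u_first && f_first))
              acc_varies <- TRUE
            if (include_end_variation || !(u_last && f_last))
              don_varies <- TRUE
          }
        }
      }
      label <- if (acc_varies && don_varies) "AE_ALT_BOTH"
      else if (acc_varies) "AE_ALT3SS"
      else if (don_varies) "AE_ALT5SS"
      else "CE"  # variation only at TSS/TES (or none)
    }

    ve <- c(if (acc_varies) "acceptor_end", if (don_varies) "donor_end")
    out[[u]] <- data.frame(
      gene_id = gene$gene_id, chrom = gene$chrom, strand = strand,
      start = s, end = e, exon_index = u, label = label,
      transcripts = paste(sort(containing), collapse = ","),
      variable_ends = paste(ve, collapse = ","))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segment a gene into constitutive and alternative exon regions
#'
#' Scheme 2: exons are dividable. Over the union of exonic bases, each
#' base's transcript coverage is computed by exact interval arithmetic;
#' maximal runs covered by every transcript are constitutive regions
#' (`CR`), runs covered by some but not all transcripts are alternative
#' regions (`AR`). The output is sorted, non-overlapping, and covers
#' exactly the exonic union.
#'
#' @param gene A `gene_model`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `label` (`CR`/`AR`), `coverage` (number of transcripts
#'   containing every base of the interval).
#' @export
segment_exon_regions <- function(gene) {
  txs <- gene$transcripts
  n_tx <- length(txs)
  ex <- do.call(rbind, lapply(txs, function(t) t$exons))
  pts <- sort(unique(c(ex$start, ex$end)))
  seg_s <- pts[-length(pts)]
  seg_e <- pts[-1L]
  cov <- vapply(seq_along(seg_s), function(i)
    sum(ex$start <= seg_s[i] & seg_e[i] <= ex$end), 0L)
  keep <- cov > 0L
  seg_s <- seg_s[keep]
  seg_e <- seg_e[keep]
  cov <- cov[keep]
  if (length(seg_s) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      coverage = integer(0)))
  lab <- ifelse(cov == n_tx, "CR", "AR")
  # merge abutting same-label segments into maximal runs
  runs <- list()
  cs <- seg_s[1L]; ce <- seg_e[1L]; cl <- lab[1L]
  for (i in seq_along(seg_s)[-1L]) {
    if (seg_s[i] == ce && lab[i] == cl) {
      ce <- seg_e[i]
    } else {
      runs[[length(runs) + 1L]] <- c(cs, ce, cl)
      cs <- seg_s[i]; ce <- seg_e[i]; cl <- lab[i]
    }
  }
  runs[[length(runs) + 1L]] <- c(cs, ce, cl)
  res <- data.frame(
    gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
    start = as.integer(vapply(runs, `[[`, "", 1L)),
    end = as.integer(vapply(runs, `[[`, "", 2L)),
    label = vapply(runs, `[[`, "", 3L))
  # coverage of a run = transcripts containing every base (a single exon
  # of the transcript must span the run)
  res$coverage <- vapply(seq_len(nrow(res)), function(i)
    sum(vapply(txs, function(t)
      any(t$exons$start <= res$start[i] & res$end[i] <= t$exons$end),
      TRUE)), 0L)
  rownames(res) <- NULL
  res
}

# semicolon-joined key=value attributes shared by a set of transcripts
common_attributes <- function(txs) {
  kv <- lapply(txs, function(t)
    paste0(names(t$attributes), "=", t$attributes))
  shared <- Reduce(intersect, kv)
  shared <- setdiff(shared, "")
  if (length(shared) == 0L) "." else paste(sort(shared), collapse = ";")
}

#' Annotate gene models under either classification scheme
#'
#' Dispatches to [classify_exons_intact()] (`scheme = "intact"`) or
#' [segment_exon_regions()] (`scheme = "regions"`) and shapes the result as
#' BED-like records ready for [write_bed_like()]. The `attributes` column
#' retains the original annotation attributes shared by the supporting
#' transcripts.
#'
#' @param genes List of `gene_model` objects (or a single one).
#' @param scheme `"intact"` or `"regions"`.
#' @param include_end_variation Passed to [classify_exons_intact()].
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`
#'   (`gene_id:feature_index`), `label`, `strand`, `transcripts`,
#'   `attributes`, ordered by (chrom, start, end, label).
#' @export
annotate_exons <- function(genes, scheme = c("intact", "regions"),
                           include_end_variation = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(genes, "gene_model"))
    genes <- list(genes)
  recs <- lapply(genes, function(g) {
    if (scheme == "intact") {
      calls <- classify_exons_intact(g, include_end_variation)
      if (nrow(calls) == 0L)
        return(NULL)
      tx_sets <- strsplit(calls$transcripts, ",", fixed = TRUE)
      data.frame(
        chrom = calls$chrom, start = calls$start, end = calls$end,
        name = paste0(g$gene_id, ":", calls$exon_index),
        label = calls$label, strand = calls$strand,
        transcripts = calls$transcripts,
        attributes = vapply(tx_sets, function(ids)
          common_attributes(g$transcripts[ids]), ""))
    } else {
      regs <- segment_exon_regions(g)
      if (nrow(regs) == 0L)
        return(NULL)
      all_ids <- sort(names(g$transcripts))
      covering <- vapply(seq_len(nrow(regs)), function(i)
        paste(sort(names(g$transcripts)[vapply(g$transcripts, function(t)
          any(t$exons$start <= regs$start[i] & regs$end[i] <= t$exons$end),
          TRUE)]), collapse = ","), "")
      data.frame(
        chrom = regs$chrom, start = regs$start, end = regs$end,
        name = paste0(g$gene_id, ":", seq_len(nrow(regs))),
        label = regs$label, strand = regs$strand,
        transcripts = covering,
        attributes = common_attributes(g$transcripts))
    }
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      label = character(0), strand = character(0),
                      transcripts = character(0), attributes = character(0)))
  recs <- recs[order(recs$chrom, recs$start, recs$end, recs$label), ,
               drop = FALSE]
  rownames(recs) <- NULL
  recs
}
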