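#' @title Synthetic gene models, genomes, and junction counts
#' @description Generates every input the package consumes: the canonical
#'   four-exon worked example (one isoform per event type), random
#'   multi-isoform genes with planted events and controllable splice-site
#'   strength, and junction count tables with known inclusion levels.
#'   Everything is deterministic for a fixed seed.
#' @name synthetic_data
NULL

plant <- function(chars, start0, motif) {
  m <- strsplit(motif, "", fixed = TRUE)[[1L]]
  chars[(start0 + 1L):(start0 + length(m))] <- m
  chars
}

#' The canonical four-exon worked example
#'
#' A deterministic five-isoform gene on `chrT` (+ strand) demonstrating one
#' event of each main type against the reference `i0` (exons at
#' `[100,200)`, `[400,500)`, `[700,790)`, `[1000,1100)`):
#' * `i1` skips exon 3 (exon skipping),
#' * `i2` starts exon 2 at 430 (alternative 3' splice site),
#' * `i3` ends exon 1 at 170 (alternative 5' splice site),
#' * `i4` retains intron 2 (merged exon `[400,790)`).
#'
#' The bundled genome has the consensus donor (`GT...`) and acceptor
#' (`...AG`) dinucleotides at every used splice site, full consensus donor
#' windows, pyrimidine-rich acceptor regions, and a `CTAAC` branch-point
#' motif 30 nt upstream of each reference acceptor. No randomness is used.
#'
#' @return List with `gene` (a `gene_model`), `genome` (a `genome_store`),
#'   and `truth` (expected events, intact-exon labels, and CR/AR regions).
#' @export
make_worked_example <- function() {
  mk <- function(id, exons)
    new_transcript(id, "gene1", "chrT", "+",
                   data.frame(start = exons[c(TRUE, FALSE)],
                              end = exons[c(FALSE, TRUE)]),
                   attributes = c(gene_id = "gene1", transcript_id = id,
                                  gene_name = "ASDEMO"))
  gene <- new_gene_model("gene1", list(
    mk("i0", c(100L, 200L, 400L, 500L, 700L, 790L, 1000L, 1100L)),
    mk("i1", c(100L, 200L, 400L, 500L, 1000L, 1100L)),
    mk("i2", c(100L, 200L, 430L, 500L, 700L, 790L, 1000L, 1100L)),
    mk("i3", c(100L, 170L, 400L, 500L, 700L, 790L, 1000L, 1100L)),
    mk("i4", c(100L, 200L, 400L, 790L, 1000L, 1100L))))

  # deterministic A/T-free background so no accidental GT/AG/YUNAY/PPT
  chars <- rep(c("C", "G", "G"), length.out = 1300L)
  for (e in c(170L, 200L, 500L, 790L))        # donor sites (exon ends)
    chars <- plant(chars, e - 3L, DONOR_CONSENSUS)
  for (s in c(400L, 430L, 700L, 1000L))       # acceptor sites (exon starts)
    chars <- plant(chars, s - 20L, ACCEPTOR_CONSENSUS)
  for (s in c(400L, 700L, 1000L))             # branch points, 30 nt upstream
    chars <- plant(chars, s - 30L, "CTAAC")
  genome <- structure(c(chrT = paste(chars, collapse = "")),
                      class = "genome_store")

  truth <- list(
    events = data.frame(
      event_type = c("ES", "A3SS", "A5SS", "IR"),
      alt_id = c("i1", "i2", "i3", "i4"),
      start = c(700L, 400L, 170L, 500L),
      end = c(790L, 430L, 200L, 700L)),
    labels = data.frame(
      start = c(100L, 100L, 400L, 400L, 430L, 700L, 1000L),
      end = c(170L, 200L, 500L, 790L, 500L, 790L, 1100L),
      label = c("AE_ALT5SS", "AE_ALT5SS", "AE_ALT3SS", "AE_IR_MERGED",
                "AE_ALT3SS", "AE_CASSETTE", "CE")),
    regions = data.frame(
      start = c(100L, 170L, 400L, 430L, 500L, 1000L),
      end = c(170L, 200L, 430L, 500L, 790L, 1100L),
      label = c("CR", "AR", "AR", "CR", "AR", "CR")))
  list(gene = gene, genome = genome, truth = truth)
}

#' Simulation specification
#'
#' The stated world of the simulator: a reference isoform with `n_exons`
#' exons, one extra isoform per planted event, a genome whose donor and
#' acceptor windows match the consensus per position with the given
#' probability (canonical `GT`/`AG` dinucleotides are always kept), and
#' junction counts at the given depth and true inclusion level. Planted
#' events are assigned to distinct, non-adjacent internal exons so truth
#' labels are single-valued.
#'
#' @param n_exons Number of reference exons (default 6).
#' @param exon_length,intron_length Length ranges, nt (defaults 90-180 and
#'   250-800: compact but realistically proportioned loci that keep tests
#'   fast).
#' @param events Character subset of `ES`, `A3SS`, `A5SS`, `IR`,
#'   `EXONIC_INTRON` (may repeat).
#' @param shift Splice-site shift size, nt, for A3SS/A5SS (default 12).
#' @param internal_intron_length Excised-region size for EXONIC_INTRON
#'   (default 40).
#' @param donor_strength,acceptor_strength Per-position probability that a
#'   splice-site window position matches the consensus (defaults 0.9).
#' @param psi True inclusion level of each cassette exon (default 0.7).
#' @param depth Junction read depth (default 100).
#' @param seed Random seed.
#' @param chrom,gene_id,strand Locus naming.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_exons = 6L, exon_length = c(90L, 180L),
                     intron_length = c(250L, 800L),
                     events = character(0), shift = 12L,
                     internal_intron_length = 40L,
                     donor_strength = 0.9, acceptor_strength = 0.9,
                     psi = 0.7, depth = 100L, seed = 1L,
                     chrom = "sim1", gene_id = "simg1", strand = "+") {
  spec <- list(n_exons = as.integer(n_exons),
               exon_length = as.integer(exon_length),
               intron_length = as.integer(intron_length),
               events = as.character(events), shift = as.integer(shift),
               internal_intron_length = as.integer(internal_intron_length),
               donor_strength = donor_strength,
               acceptor_strength = acceptor_strength,
               psi = psi, depth = as.integer(depth), seed = as.integer(seed),
               chrom = chrom, gene_id = gene_id, strand = strand)
  if (any(!spec$events %in% EVENT_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(spec$events, EVENT_TYPES), collapse = ", "))
  if (spec$n_exons < 3L && length(spec$events) > 0L)
    stop("infeasible spec: events need internal exons (n_exons >= 3)")
  if (any(spec$exon_length < 1L) || any(spec$intron_length < 1L))
    stop("infeasible spec: lengths must be positive")
  if (spec$shift >= spec$exon_length[1L])
    stop("infeasible spec: shift (", spec$shift,
         ") >= minimum exon length (", spec$exon_length[1L], ")")
  if (spec$shift >= spec$intron_length[1L])
    stop("infeasible spec: shift (", spec$shift,
         ") >= minimum intron length (", spec$intron_length[1L], ")")
  if ("EXONIC_INTRON" %in% spec$events &&
      spec$exon_length[1L] < spec$internal_intron_length + 20L)
    stop("infeasible spec: exons too short for the internal intron")
  if (any(spec$psi < 0) || any(spec$psi > 1))
    stop("infeasible spec: psi must lie in [0, 1]")
  if (!spec$strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(spec, class = "sim_spec")
}

# assign each event to an internal reference exon, keeping one untouched
# exon between assignments (IR occupies two exons)
assign_event_exons <- function(spec) {
  internal <- seq(2L, spec$n_exons - 1L)
  out <- integer(0)
  nxt <- 1L
  for (ev in spec$events) {
    width <- if (ev == "IR") 2L else 1L
    if (nxt + width - 1L > length(internal))
      stop("infeasible spec: not enough internal exons for ",
           length(spec$events), " event(s); increase n_exons")
    out <- c(out, internal[nxt])
    nxt <- nxt + width + 1L  # leave a gap exon
  }
  out
}

# variable-end label in transcription direction for a boundary at the
# genomic left (side = "start") or right (side = "end") of an exon
boundary_label <- function(side, strand) {
  donor <- (side == "end") == (strand == "+")
  if (donor) "AE_ALT5SS" else "AE_ALT3SS"
}

#' Simulate a gene model, genome, and truth record
#'
#' Builds the reference isoform `i0`, one alternative isoform per planted
#' event (`i1`, `i2`, ...), and a genome whose splice-site windows are
#' drawn per position from the donor/acceptor consensus with probability
#' equal to the configured strength (background positions are uniform
#' random; reference-isoform sites are planted last so their canonical
#' `GT`/`AG` dinucleotides are always intact). Reproducible for a fixed
#' seed.
#'
#' Note the `EXONIC_INTRON` duality: the isoform that splices out an
#' internal exon region has more exons than the intact one, so it is, by
#' definition, selected as the gene's reference isoform; gene-level event
#' detection then reports the dual IR event. The truth record therefore
#' stores the planted ref/alt orientation explicitly.
#'
#' @param spec A [sim_spec()].
#' @return List with `gene`, `genome`, `truth` (`events` with `ref_id` and
#'   `alt_id`, per-unit `labels`, cassette-exon `psi`), and `spec`.
#' @export
simulate_gene <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_exons
  ex_len <- sample(seq(spec$exon_length[1L], spec$exon_length[2L]), n,
                   replace = TRUE)
  in_len <- if (n > 1L)
    sample(seq(spec$intron_length[1L], spec$intron_length[2L]), n - 1L,
           replace = TRUE) else integer(0)
  margin <- 400L
  starts <- integer(n)
  ends <- integer(n)
  pos <- margin
  for (k in seq_len(n)) {
    starts[k] <- pos
    ends[k] <- pos + ex_len[k]
    pos <- ends[k] + if (k < n) in_len[k] else 0L
  }
  ref_ex <- data.frame(start = starts, end = ends)
  event_exon <- assign_event_exons(spec)

  mk <- function(id, exons)
    new_transcript(id, spec$gene_id, spec$chrom, spec$strand, exons,
                   attributes = c(gene_id = spec$gene_id,
                                  transcript_id = id))
  txs <- list(i0 = mk("i0", ref_ex))
  truth_events <- list()
  truth_labels <- list()
  add_label <- function(s, e, lab)
    truth_labels[[length(truth_labels) + 1L]] <<-
      data.frame(start = s, end = e, label = lab)
  cassette <- data.frame(start = integer(0), end = integer(0))

  for (vi in seq_along(spec$events)) {
    ev <- spec$events[vi]
    k <- event_exon[vi]
    id <- paste0("i", vi)
    s <- ref_ex$start[k]
    e <- ref_ex$end[k]
    if (ev == "ES") {
      txs[[id]] <- mk(id, ref_ex[-k, ])
      add_label(s, e, "AE_CASSETTE")
      cassette <- rbind(cassette, data.frame(start = s, end = e))
      ev_int <- c(s, e)
      ref_id <- "i0"
    } else if (ev == "A3SS") {
      # acceptor-side shift (transcription direction)
      alt_ex <- ref_ex
      if (spec$strand == "+") {
        alt_ex$start[k] <- s + spec$shift
        ev_int <- c(s, s + spec$shift)
        add_label(s + spec$shift, e, "AE_ALT3SS")
      } else {
        alt_ex$end[k] <- e - spec$shift
        ev_int <- c(e - spec$shift, e)
        add_label(s, e - spec$shift, "AE_ALT3SS")
      }
      add_label(s, e, "AE_ALT3SS")
      txs[[id]] <- mk(id, alt_ex)
      ref_id <- "i0"
    } else if (ev == "A5SS") {
      alt_ex <- ref_ex
      if (spec$strand == "+") {
        alt_ex$end[k] <- e - spec$shift
        ev_int <- c(e - spec$shift, e)
        add_label(s, e - spec$shift, "AE_ALT5SS")
      } else {
        alt_ex$start[k] <- s + spec$shift
        ev_int <- c(s, s + spec$shift)
        add_label(s + spec$shift, e, "AE_ALT5SS")
      }
      add_label(s, e, "AE_ALT5SS")
      txs[[id]] <- mk(id, alt_ex)
      ref_id <- "i0"
    } else if (ev == "IR") {
      e2 <- ref_ex$end[k + 1L]
      alt_ex <- ref_ex[-(k + 1L), ]
      alt_ex$end[k] <- e2
      txs[[id]] <- mk(id, alt_ex)
      ev_int <- c(e, ref_ex$start[k + 1L])
      add_label(s, e2, "AE_IR_MERGED")
      add_label(s, e, boundary_label("end", spec$strand))
      add_label(ref_ex$start[k + 1L], e2, boundary_label("start", spec$strand))
      ref_id <- "i0"
    } else { # EXONIC_INTRON
      g <- spec$internal_intron_length
      c0 <- s + ((e - s - g) %/% 2L)
      d0 <- c0 + g
      alt_ex <- rbind(ref_ex[seq_len(k - 1L), ],
                      data.frame(start = c(s, d0), end = c(c0, e)),
                      ref_ex[seq(k + 1L, n), ])
      txs[[id]] <- mk(id, alt_ex)
      ev_int <- c(c0, d0)
      add_label(s, e, "AE_IR_MERGED")
      add_label(s, c0, boundary_label("end", spec$strand))
      add_label(d0, e, boundary_label("start", spec$strand))
      ref_id <- "i0"
    }
    truth_events[[vi]] <- data.frame(
      event_type = ev, ref_id = ref_id, alt_id = id,
      start = as.integer(ev_int[1L]), end = as.integer(ev_int[2L]))
  }
  gene <- new_gene_model(spec$gene_id, txs)

  # remaining reference exons are constitutive
  labelled <- if (length(truth_labels))
    do.call(rbind, truth_labels) else
      data.frame(start = integer(0), end = integer(0), label = character(0))
  for (k in seq_len(n)) {
    s <- ref_ex$start[k]
    e <- ref_ex$end[k]
    if (!any(labelled$start == s & labelled$end == e))
      add_label(s, e, "CE")
  }
  labels <- do.call(rbind, truth_labels)
  labels <- unique(labels[order(labels$start, labels$end), , drop = FALSE])
  rownames(labels) <- NULL

  # genome: uniform background, then splice-site windows (variant isoform
  # sites first, reference sites last so i0 boundaries stay canonical)
  L <- max(vapply(txs, function(t) max(t$exons$end), 0L)) + margin
  chars <- sample(DNA_BASES, L, replace = TRUE)
  realize <- function(consensus, strength, force_idx, force_chars) {
    cc <- strsplit(consensus, "", fixed = TRUE)[[1L]]
    out <- vapply(cc, function(b)
      if (stats::runif(1L) < strength) b else sample(DNA_BASES, 1L), "")
    out[force_idx] <- force_chars
    paste(out, collapse = "")
  }
  plant_sites <- function(chars, tx) {
    it <- introns(tx)
    for (j in seq_len(nrow(it))) {
      don <- intron_donor(it$start[j], it$end[j], spec$strand)
      acc <- intron_acceptor(it$start[j], it$end[j], spec$strand)
      dw <- realize(DONOR_CONSENSUS, spec$donor_strength, 4:5, c("G", "T"))
      aw <- realize(ACCEPTOR_CONSENSUS, spec$acceptor_strength, 19:20,
                    c("A", "G"))
      if (spec$strand == "+") {
        chars <- plant(chars, don - 3L, dw)
        chars <- plant(chars, acc - 20L, aw)
      } else {
        chars <- plant(chars, don - 6L, revcomp(dw))
        chars <- plant(chars, acc - 3L, revcomp(aw))
      }
    }
    chars
  }
  for (id in setdiff(names(txs), "i0"))
    chars <- plant_sites(chars, txs[[id]])
  chars <- plant_sites(chars, txs[["i0"]])
  genome <- structure(
    stats::setNames(paste(chars, collapse = ""), spec$chrom),
    class = "genome_store")

  truth <- list(
    events = if (length(truth_events)) do.call(rbind, truth_events) else
      data.frame(event_type = character(0), ref_id = character(0),
                 alt_id = character(0), start = integer(0),
                 end = integer(0)),
    labels = labels,
    cassette = cassette,
    psi = rep_len(spec$psi, nrow(cassette)))
  list(gene = gene, genome = genome, truth = truth, spec = spec)
}

#' Simulate junction read counts with known inclusion levels
#'
#' Every intron of the reference isoform receives `depth` supporting
#' reads, except around each alternative cassette exon: there, the number
#' of included transcripts is drawn once as `Binomial(depth, psi)`, both
#' inclusion junctions receive that coverage (every included fragment pool
#' spans both junctions at the event depth, as spliced mapping does), and
#' the remaining `depth - inclusion` reads support the skip junction, so
#' inclusion and exclusion stay on the same per-event scale.
#'
#' @param gene A `gene_model`.
#' @param psi True inclusion level(s), recycled across cassette exons in
#'   genomic order.
#' @param depth Read depth per splicing event.
#' @param seed Random seed.
#' @param path Optional output TSV (simple dialect, see
#'   [read_junctions()]).
#' @return Junction `data.frame` (`chrom`, `start`, `end`, `strand`,
#'   `count`), invisibly when `path` is given.
#' @export
simulate_junction_counts <- function(gene, psi, depth, seed = 1L,
                                     path = NULL) {
  set.seed(seed)
  ref <- gene$transcripts[[select_reference_isoform(gene)]]
  rex <- ref$exons
  ri <- introns(ref)
  calls <- classify_exons_intact(gene)
  cass <- calls[calls$label == "AE_CASSETTE", , drop = FALSE]
  # cassette exons that are internal reference exons, genomic order
  kidx <- vapply(seq_len(nrow(cass)), function(i) {
    k <- which(rex$start == cass$start[i] & rex$end == cass$end[i])
    if (length(k) == 1L && k > 1L && k < nrow(rex)) k else NA_integer_
  }, 0L)
  kidx <- sort(kidx[!is.na(kidx)])
  psi <- rep_len(psi, max(length(kidx), 1L))
  counts <- rep(as.integer(depth), nrow(ri))
  skip_rows <- list()
  for (i in seq_along(kidx)) {
    k <- kidx[i]
    incl <- stats::rbinom(1L, as.integer(depth), psi[i])
    counts[k - 1L] <- incl
    counts[k] <- incl
    skip_rows[[i]] <- data.frame(
      chrom = gene$chrom, start = rex$end[k - 1L], end = rex$start[k + 1L],
      strand = gene$strand, count = as.integer(depth) - incl)
  }
  tab <- rbind(
    if (nrow(ri)) data.frame(chrom = gene$chrom, start = ri$start,
                             end = ri$end, strand = gene$strand,
                             count = counts) else NULL,
    if (length(skip_rows)) do.call(rbind, skip_rows) else NULL)
  if (is.null(tab))
    tab <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      count = integer(0))
  tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    writeLines(c("#chrom\tstart\tend\tstrand\tcount",
                 sprintf("%s\t%d\t%d\t%s\t%d", tab$chrom, tab$start,
                         tab$end, tab$strand, tab$count)), path)
    return(invisible(tab))
  }
  tab
}
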