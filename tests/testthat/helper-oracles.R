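# Independent brute-force oracles used by the property suites. These
# favour per-base logical vectors and exhaustive enumeration over the
# package's breakpoint/index arithmetic, so shared bugs are unlikely.

# logical per-base coverage of a transcript over [lo, hi)
tx_base_cov <- function(tx, lo, hi) {
  v <- logical(hi - lo)
  for (k in seq_len(nrow(tx$exons))) {
    a <- max(tx$exons$start[k], lo)
    b <- min(tx$exons$end[k], hi)
    if (b > a)
      v[(a - lo + 1L):(b - lo)] <- TRUE
  }
  v
}

gene_bounds <- function(gene) {
  starts <- unlist(lapply(gene$transcripts, function(t) t$exons$start))
  ends <- unlist(lapply(gene$transcripts, function(t) t$exons$end))
  c(min(starts), max(ends))
}

# per-base counting oracle for CR/AR segmentation
oracle_segment <- function(gene) {
  b <- gene_bounds(gene)
  lo <- b[1L]; hi <- b[2L]
  covm <- vapply(gene$transcripts, tx_base_cov, logical(hi - lo), lo, hi)
  if (is.null(dim(covm)))
    covm <- matrix(covm, ncol = length(gene$transcripts))
  cov <- rowSums(covm)
  n <- length(gene$transcripts)
  lab <- ifelse(cov == 0L, "NONE", ifelse(cov == n, "CR", "AR"))
  r <- rle(lab)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values != "NONE"
  out <- data.frame(start = lo + run_start[keep] - 1L,
                    end = lo + run_end[keep],
                    label = r$values[keep])
  out$coverage <- vapply(seq_len(nrow(out)), function(i) {
    idx <- (out$start[i] - lo + 1L):(out$end[i] - lo)
    sum(apply(covm[idx, , drop = FALSE], 2L, all))
  }, 0L)
  out
}

# per-base intron runs of a transcript (gaps strictly inside its span)
oracle_introns <- function(tx) {
  lo <- min(tx$exons$start); hi <- max(tx$exons$end)
  v <- tx_base_cov(tx, lo, hi)
  r <- rle(v)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- !r$values
  data.frame(start = lo + run_start[keep] - 1L, end = lo + run_end[keep])
}

# brute-force event detection from first principles
oracle_events <- function(ref, alt) {
  strand <- ref$strand
  rex <- ref$exons; aex <- alt$exons
  ri <- oracle_introns(ref); ai <- oracle_introns(alt)
  grid_ev <- list()
  emit <- function(type, s, e)
    grid_ev[[length(grid_ev) + 1L]] <<- data.frame(
      event_type = type, start = s, end = e)
  within <- function(s1, e1, s2, e2) s2 <= s1 && e1 <= e2
  inside <- function(s1, e1, s2, e2) s2 < s1 && e1 < e2
  for (k in seq_len(nrow(rex))) for (j in seq_len(nrow(ai)))
    if (within(rex$start[k], rex$end[k], ai$start[j], ai$end[j]))
      emit("ES", rex$start[k], rex$end[k])
  for (k in seq_len(nrow(aex))) {
    hit_s <- rex$start == aex$start[k]
    hit_e <- rex$end == aex$end[k]
    if (sum(hit_s) == 1L && sum(hit_e) == 1L &&
        which(hit_e) > which(hit_s))
      for (j in which(hit_s):(which(hit_e) - 1L))
        emit("IR", ri$start[j], ri$end[j])
  }
  for (j in seq_len(nrow(ai))) for (k in seq_len(nrow(rex)))
    if (inside(ai$start[j], ai$end[j], rex$start[k], rex$end[k]))
      emit("EXONIC_INTRON", ai$start[j], ai$end[j])
  don <- function(df, i) if (strand == "+") df$start[i] else df$end[i]
  acc <- function(df, i) if (strand == "+") df$end[i] else df$start[i]
  skips_exon <- function(s, e, ex)
    any(vapply(seq_len(nrow(ex)), function(k)
      within(ex$start[k], ex$end[k], s, e), TRUE))
  for (j in seq_len(nrow(ai))) {
    if (skips_exon(ai$start[j], ai$end[j], rex)) next
    for (i in seq_len(nrow(ri))) {
      if (skips_exon(ri$start[i], ri$end[i], aex)) next
      if (don(ri, i) == don(ai, j) && acc(ri, i) != acc(ai, j))
        emit("A3SS", min(acc(ri, i), acc(ai, j)),
             max(acc(ri, i), acc(ai, j)))
      if (acc(ri, i) == acc(ai, j) && don(ri, i) != don(ai, j))
        emit("A5SS", min(don(ri, i), don(ai, j)),
             max(don(ri, i), don(ai, j)))
    }
  }
  if (length(grid_ev) == 0L)
    return(data.frame(event_type = character(0), start = integer(0),
                      end = integer(0)))
  out <- unique(do.call(rbind, grid_ev))
  out[order(out$start, out$end, out$event_type), , drop = FALSE]
}

# overlap-allowed k-mer counting by position loop
oracle_scan <- function(seq, kmer) {
  n <- nchar(seq); k <- nchar(kmer)
  hits <- integer(0)
  if (n >= k)
    for (p in 1:(n - k + 1L))
      if (substr(seq, p, p + k - 1L) == kmer)
        hits <- c(hits, p - 1L)
  hits
}

# exhaustive branch-point scan: all YUNAY matches, then the closest
# within [min_distance, hard_max]
oracle_bp <- function(seq, min_distance = 14L, hard_max = 350L) {
  L <- nchar(seq)
  dists <- integer(0)
  for (p in seq_len(max(L - 4L, 0L))) {
    m <- substr(seq, p, p + 4L)
    if (grepl("^[CT]T[ACGT]A[CT]$", m))
      dists <- c(dists, L - p + 1L)
  }
  dists <- dists[dists >= min_distance & dists <= hard_max]
  if (length(dists) == 0L) NULL else min(dists)
}

# exhaustive PPT enumeration over every (start, length) pair
oracle_ppt <- function(seq, min_fraction = 0.7, min_length = 10L,
                       search_span = 50L, gap = 2L) {
  L <- nchar(seq)
  if (L < 10L) return(NULL)
  lo <- max(1L, L - search_span + 1L)
  hi <- L - 2L - gap
  cand <- list()
  for (s in lo:hi) for (e in s:hi) {
    len <- e - s + 1L
    if (len < min_length) next
    sub <- substr(seq, s, e)
    frac <- mean(strsplit(sub, "")[[1L]] %in% c("C", "T"))
    if (frac >= min_fraction)
      cand[[length(cand) + 1L]] <- c(s, len, frac)
  }
  if (length(cand) == 0L) return(NULL)
  tab <- do.call(rbind, cand)
  tab <- tab[order(-tab[, 2L], -(tab[, 1L] + tab[, 2L])), , drop = FALSE]
  list(start = unname(tab[1L, 1L]) - 1L, length = unname(tab[1L, 2L]),
       pyrimidine_fraction = unname(tab[1L, 3L]))
}

# mirror a gene model (and optionally its genome) through position L:
# coordinates flip, strand flips, sequence reverse-complements
mirror_gene <- function(gene, L) {
  flip_strand <- if (gene$strand == "+") "-" else "+"
  txs <- lapply(gene$transcripts, function(tx)
    new_transcript(tx$transcript_id, tx$gene_id, tx$chrom, flip_strand,
                   data.frame(start = L - rev(tx$exons$end),
                              end = L - rev(tx$exons$start)),
                   attributes = tx$attributes))
  new_gene_model(gene$gene_id, txs)
}

mirror_genome <- function(genome) {
  structure(setNames(revcomp(unclass(genome)), names(genome)),
            class = "genome_store")
}

# random simulated gene drawing 1-3 planted events; strand alternates
random_sim_gene <- function(seed) {
  set.seed(seed * 7L + 1L)
  n_ev <- sample(0:3, 1L)
  evs <- if (n_ev > 0L)
    sample(c("ES", "A3SS", "A5SS", "IR", "EXONIC_INTRON"), n_ev,
           replace = TRUE) else character(0)
  strand <- sample(c("+", "-"), 1L)
  simulate_gene(sim_spec(n_exons = 4L + 2L * length(evs) + sample(0:2, 1L),
                         events = evs, strand = strand,
                         seed = seed, shift = sample(8:20, 1L)))
}

expect_same_regions <- function(got, want) {
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$label, want$label)
  expect_equal(got$coverage, want$coverage)
}

# label oracle: derives intact-unit labels from per-base coverage plus the
# pairwise event oracle (assumes no TSS/TES-only variation, which the
# simulator never plants)
oracle_classify <- function(gene) {
  txs <- gene$transcripts
  n_tx <- length(txs)
  strand <- gene$strand
  units <- unique(do.call(rbind, lapply(txs, function(t) t$exons)))
  units <- units[order(units$start, units$end), , drop = FALSE]
  merged_unit <- function(s, e) any(vapply(txs, function(t) {
    v <- tx_base_cov(t, s, e)
    v[1L] && v[length(v)] && !all(v) &&
      s %in% t$exons$start && e %in% t$exons$end
  }, TRUE))
  labs <- character(nrow(units))
  for (u in seq_len(nrow(units))) {
    s <- units$start[u]; e <- units$end[u]
    containing <- names(txs)[vapply(txs, function(t)
      any(t$exons$start == s & t$exons$end == e), TRUE)]
    if (length(containing) == n_tx) { labs[u] <- "CE"; next }
    if (merged_unit(s, e)) { labs[u] <- "AE_IR_MERGED"; next }
    cass <- any(vapply(txs, function(t) {
      lo <- min(t$exons$start); hi <- max(t$exons$end)
      s >= lo && e <= hi && !any(tx_base_cov(t, s, e))
    }, TRUE))
    if (cass) { labs[u] <- "AE_CASSETTE"; next }
    acc_u <- if (strand == "+") s else e
    don_u <- if (strand == "+") e else s
    acc_v <- don_v <- FALSE
    for (t1 in containing) for (t2 in setdiff(names(txs), t1)) {
      ev <- oracle_events(txs[[t1]], txs[[t2]])
      ev3 <- ev[ev$event_type == "A3SS", , drop = FALSE]
      ev5 <- ev[ev$event_type == "A5SS", , drop = FALSE]
      for (i in seq_len(nrow(ev3)))
        if (acc_u %in% c(ev3$start[i], ev3$end[i])) {
          other <- setdiff(c(ev3$start[i], ev3$end[i]), acc_u)
          side <- if (strand == "+") "start" else "end"
          ex2 <- txs[[t2]]$exons
          k <- if (side == "start") which(ex2$start == other) else
            which(ex2$end == other)
          if (!(length(k) == 1L && merged_unit(ex2$start[k], ex2$end[k])))
            acc_v <- TRUE
        }
      for (i in seq_len(nrow(ev5)))
        if (don_u %in% c(ev5$start[i], ev5$end[i])) {
          other <- setdiff(c(ev5$start[i], ev5$end[i]), don_u)
          side <- if (strand == "+") "end" else "start"
          ex2 <- txs[[t2]]$exons
          k <- if (side == "end") which(ex2$end == other) else
            which(ex2$start == other)
          if (!(length(k) == 1L && merged_unit(ex2$start[k], ex2$end[k])))
            don_v <- TRUE
        }
    }
    if (!acc_v && !don_v) {
      # fallback: direct overlap comparison (IR / exonic-intron flanks)
      for (t2 in setdiff(names(txs), containing)) {
        ex2 <- txs[[t2]]$exons
        for (k in seq_len(nrow(ex2))) {
          if (ex2$end[k] <= s || e <= ex2$start[k]) next
          acc_f <- if (strand == "+") ex2$start[k] else ex2$end[k]
          don_f <- if (strand == "+") ex2$end[k] else ex2$start[k]
          if (acc_u != acc_f) acc_v <- TRUE
          if (don_u != don_f) don_v <- TRUE
        }
      }
    }
    labs[u] <- if (acc_v && don_v) "AE_ALT_BOTH" else if (acc_v)
      "AE_ALT3SS" else if (don_v) "AE_ALT5SS" else "CE"
  }
  data.frame(start = units$start, end = units$end, label = labs)
}
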