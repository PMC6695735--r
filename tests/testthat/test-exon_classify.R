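wx <- make_worked_example()

test_that("reference isoform selection follows exon count, length, then id", {
  expect_equal(select_reference_isoform(wx$gene), "i0")
  one <- new_gene_model("g", list(
    new_transcript("only", "g", "c", "+",
                   data.frame(start = 0L, end = 30L))))
  expect_equal(select_reference_isoform(one), "only")
  # equal exon count, summed lengths 400 vs 380
  tie <- new_gene_model("g", list(
    new_transcript("tb", "g", "c", "+",
                   data.frame(start = c(0L, 500L), end = c(200L, 700L))),
    new_transcript("ta", "g", "c", "+",
                   data.frame(start = c(0L, 500L), end = c(190L, 690L)))))
  expect_equal(select_reference_isoform(tie), "tb")
  # full tie -> lexicographically smallest id
  tie2 <- new_gene_model("g", list(
    new_transcript("z", "g", "c", "+", data.frame(start = 0L, end = 10L)),
    new_transcript("a", "g", "c", "+", data.frame(start = 0L, end = 10L))))
  expect_equal(select_reference_isoform(tie2), "a")
})

test_that("the worked gene yields one event of each type against i0", {
  ev <- gene_events(wx$gene)
  expect_equal(nrow(ev), 4L)
  expect_setequal(ev$event_type, c("ES", "A3SS", "A5SS", "IR"))
  got <- ev[order(ev$alt_id), c("event_type", "alt_id", "start", "end")]
  want <- wx$truth$events[order(wx$truth$events$alt_id), ]
  expect_equal(got$event_type, want$event_type)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("event detection is empty on identity and errors across genes", {
  i0 <- wx$gene$transcripts$i0
  expect_equal(nrow(detect_events(i0, i0)), 0L)
  other <- new_transcript("x", "other_gene", "chrT", "+",
                          data.frame(start = 0L, end = 10L))
  expect_error(detect_events(i0, other), "different genes")
})

test_that("intact classification reproduces the worked-example labels", {
  calls <- classify_exons_intact(wx$gene)
  m <- merge(calls, wx$truth$labels, by = c("start", "end"))
  expect_equal(nrow(m), nrow(calls))
  expect_equal(m$label.x, m$label.y)
  # variable ends point at the competing boundary only
  expect_equal(calls$variable_ends[calls$start == 400 & calls$end == 500],
               "acceptor_end")
  expect_equal(calls$variable_ends[calls$start == 100 & calls$end == 200],
               "donor_end")
})

test_that("single-transcript genes are entirely constitutive", {
  g <- new_gene_model("g", list(
    new_transcript("t", "g", "c", "-",
                   data.frame(start = c(0L, 100L, 200L),
                              end = c(50L, 150L, 260L)))))
  expect_equal(unique(classify_exons_intact(g)$label), "CE")
  regs <- segment_exon_regions(g)
  expect_equal(regs$label, rep("CR", 3L))
  expect_equal(regs$coverage, rep(1L, 3L))
})

test_that("region segmentation matches the worked-example truth", {
  regs <- segment_exon_regions(wx$gene)
  expect_equal(regs$start, wx$truth$regions$start)
  expect_equal(regs$end, wx$truth$regions$end)
  expect_equal(regs$label, wx$truth$regions$label)
})

test_that("TSS/TES-only variation is not alternative unless requested", {
  mk <- function(id, s1)
    new_transcript(id, "g", "c", "+",
                   data.frame(start = c(s1, 300L), end = c(200L, 400L)))
  g <- new_gene_model("g", list(mk("t1", 0L), mk("t2", 50L)))
  calls <- classify_exons_intact(g)
  expect_equal(unique(calls$label), "CE")
  calls2 <- classify_exons_intact(g, include_end_variation = TRUE)
  first <- calls2[calls2$end == 200L, ]
  expect_true(all(first$label == "AE_ALT3SS"))
})

test_that("duplicating a transcript changes no label; a novel one may", {
  sim <- random_sim_gene(11)
  g <- sim$gene
  dup <- g$transcripts[[1L]]
  dup2 <- new_transcript("dup_of_first", dup$gene_id, dup$chrom, dup$strand,
                         dup$exons, dup$attributes)
  g2 <- new_gene_model(g$gene_id, c(g$transcripts, list(dup2)))
  c1 <- classify_exons_intact(g)
  c2 <- classify_exons_intact(g2)
  expect_equal(c1$label, c2$label)
  # adding a skipping isoform converts an internal CE exon to a cassette
  ref <- g$transcripts[[select_reference_isoform(g)]]
  ce <- c1[c1$label == "CE", ]
  internal <- vapply(seq_len(nrow(ce)), function(i) {
    k <- which(ref$exons$start == ce$start[i] & ref$exons$end == ce$end[i])
    length(k) == 1L && k > 1L && k < nrow(ref$exons)
  }, TRUE)
  ce <- ce[internal, ][1, ]
  k <- which(ref$exons$start == ce$start & ref$exons$end == ce$end)
  skip_tx <- new_transcript("novel_skip", g$gene_id, g$chrom, g$strand,
                            ref$exons[-k, ])
  g3 <- new_gene_model(g$gene_id, c(g$transcripts, list(skip_tx)))
  c3 <- classify_exons_intact(g3)
  expect_equal(
    c3$label[c3$start == ce$start[1] & c3$end == ce$end[1]], "AE_CASSETTE")
})

test_that("classification and events match oracles on random genes", {
  for (seed in 1:12) {
    sim <- random_sim_gene(seed)
    got <- classify_exons_intact(sim$gene)
    want <- oracle_classify(sim$gene)
    expect_equal(got$label, want$label, info = paste("seed", seed))
    ids <- names(sim$gene$transcripts)
    ref <- sim$gene$transcripts[[ids[1L]]]
    for (id in ids[-1L]) {
      ev <- detect_events(ref, sim$gene$transcripts[[id]])
      ov <- oracle_events(ref, sim$gene$transcripts[[id]])
      expect_equal(ev[, c("event_type", "start", "end")],
                   ov[, c("event_type", "start", "end")],
                   ignore_attr = TRUE, info = paste("seed", seed, id))
    }
  }
})

test_that("segmentation matches the per-base oracle on random genes", {
  for (seed in 21:35) {
    sim <- random_sim_gene(seed)
    expect_same_regions(segment_exon_regions(sim$gene),
                        oracle_segment(sim$gene))
  }
})

test_that("CR/AR regions partition the exonic union", {
  for (seed in 41:50) {
    sim <- random_sim_gene(seed)
    regs <- segment_exon_regions(sim$gene)
    expect_true(all(regs$start < regs$end))
    expect_true(all(regs$start[-1L] >= regs$end[-nrow(regs)]))
    b <- gene_bounds(sim$gene)
    exonic <- rowSums(vapply(sim$gene$transcripts, tx_base_cov,
                             logical(b[2] - b[1]), b[1], b[2])) > 0
    covered <- logical(b[2] - b[1])
    for (i in seq_len(nrow(regs)))
      covered[(regs$start[i] - b[1] + 1L):(regs$end[i] - b[1])] <- TRUE
    expect_identical(covered, unname(exonic))
  }
})

test_that("schemes are mutually consistent", {
  for (seed in c(3, 17, 29)) {
    sim <- random_sim_gene(seed)
    calls <- classify_exons_intact(sim$gene)
    regs <- segment_exon_regions(sim$gene)
    cr <- regs[regs$label == "CR", ]
    # every base of a CE exon lies in a CR region
    for (i in which(calls$label == "CE"))
      expect_true(any(cr$start <= calls$start[i] & calls$end[i] <= cr$end))
    # every AR base lies inside some non-CE unit
    ae <- calls[calls$label != "CE", ]
    for (i in which(regs$label == "AR")) {
      for (p in seq(regs$start[i], regs$end[i] - 1L))
        expect_true(any(ae$start <= p & p < ae$end))
    }
  }
})

test_that("annotate dispatches schemes and handles empty input", {
  expect_equal(nrow(annotate_exons(list(), "intact")), 0L)
  expect_error(annotate_exons(wx$gene, "bogus"))
  intact <- annotate_exons(wx$gene, "intact")
  expect_equal(nrow(intact), 7L)  # 7 distinct exon-coordinate tuples
  expect_setequal(unique(intact$label),
                  c("AE_ALT5SS", "AE_ALT3SS", "AE_CASSETTE", "CE",
                    "AE_IR_MERGED"))
  regions <- annotate_exons(wx$gene, "regions")
  expect_equal(regions$label, wx$truth$regions$label)
})

test_that("strand mirroring preserves labels, events, and segmentation", {
  L <- 2000L
  mg <- mirror_gene(wx$gene, L)
  ev <- gene_events(mg)
  expect_setequal(ev$event_type, c("ES", "A3SS", "A5SS", "IR"))
  calls <- classify_exons_intact(mg)
  want <- wx$truth$labels
  m <- merge(calls,
             data.frame(start = L - want$end, end = L - want$start,
                        label = want$label), by = c("start", "end"))
  expect_equal(nrow(m), nrow(calls))
  expect_equal(m$label.x, m$label.y)
  regs <- segment_exon_regions(mg)
  wr <- wx$truth$regions
  expect_equal(regs$start, sort(L - wr$end))
  expect_equal(regs$label, rev(wr$label))
})
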