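wx <- make_worked_example()

test_that("site windows span the boundary with the stated geometry", {
  tx <- wx$gene$transcripts$i0
  w <- extract_site_window(wx$genome, tx, 1, "donor")
  expect_equal(nchar(w), 9L)
  expect_equal(w, "CAGGTAAGT")
  # -3..-1 exonic, +1..+6 intronic around the exon end at 200
  expect_equal(w, paste0(substr(wx$genome[["chrT"]], 198, 200),
                         substr(wx$genome[["chrT"]], 201, 206)))
  a <- extract_site_window(wx$genome, tx, 2, "acceptor")
  expect_equal(nchar(a), 23L)
  expect_equal(substr(a, 19, 20), "AG")  # canonical intron terminus
  expect_error(extract_site_window(wx$genome, tx, 1, "acceptor"),
               "no splice site")
  expect_error(extract_site_window(wx$genome, tx, 4, "donor"),
               "no splice site")
})

test_that("minus-strand windows read identically on a mirrored locus", {
  L <- nchar(wx$genome[["chrT"]])
  mg <- mirror_gene(wx$gene, L)
  mgen <- mirror_genome(wx$genome)
  for (k in 1:3) {
    expect_equal(extract_site_window(mgen, mg$transcripts$i0, k, "donor"),
                 extract_site_window(wx$genome, wx$gene$transcripts$i0, k,
                                     "donor"))
    expect_equal(
      extract_site_window(mgen, mg$transcripts$i0, k + 1, "acceptor"),
      extract_site_window(wx$genome, wx$gene$transcripts$i0, k + 1,
                          "acceptor"))
  }
})

test_that("PWM training arithmetic is exact", {
  # indicator matrix from identical windows at alpha 0
  pwm <- train_pwm(rep("CAGGTAAGT", 100), "donor", alpha = 0)
  expect_equal(pwm$freq[cbind(match(strsplit("CAGGTAAGT", "")[[1]],
                                    c("A", "C", "G", "T")), 1:9)],
               rep(1, 9))
  # uniform training data gives uniform frequencies
  rot <- c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG", "TTTTTTTTT")
  pwm_u <- train_pwm(rot, "donor", alpha = 0)
  expect_true(all(abs(pwm_u$freq - 0.25) < 1e-12))
  # pseudocount: n = 3 windows, alpha = 1 -> (count + 1) / 7
  pwm_a <- train_pwm(c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC"), "donor",
                     alpha = 1)
  expect_equal(unname(pwm_a$freq["A", 1]), 3 / 7)
  expect_equal(unname(pwm_a$freq["C", 1]), 2 / 7)
  expect_equal(unname(pwm_a$freq["G", 1]), 1 / 7)
  expect_error(train_pwm(character(0), "donor"), "no training windows")
  expect_error(train_pwm(c("AAA", "AAAA"), "donor"), "length")
  expect_error(train_pwm("AAAA", "donor"), "9 nt")
})

test_that("log-odds scoring matches closed forms and a naive oracle", {
  ind <- train_pwm(rep("CAGGTAAGT", 5), "donor", alpha = 0)
  expect_equal(score_site(ind, "CAGGTAAGT"), 9 * log2(1 / 0.25)) # 18 bits
  rot <- c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG", "TTTTTTTTT")
  unif <- train_pwm(rot, "donor", alpha = 0)
  expect_equal(score_site(unif, "GTAAGTCAG"), 0)
  expect_true(is.na(score_site(ind, "CAGGTNAGT")))
  expect_error(score_site(ind, "CAGGTAAGX"), "invalid character")
  # positionwise oracle on random windows
  set.seed(99)
  win <- replicate(25, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                             collapse = ""))
  pwm <- train_pwm(win, "donor", alpha = 1)
  for (w in win[1:5]) {
    chars <- strsplit(w, "")[[1]]
    manual <- sum(vapply(seq_len(9), function(i)
      log2(pwm$freq[chars[i], i] / 0.25), 0))
    expect_equal(score_site(pwm, w), manual)
  }
})

test_that("PWM consensus attains the supremum score", {
  for (seed in 1:10) {
    set.seed(seed)
    win <- replicate(20, paste(sample(c("A", "C", "G", "T"), 9, TRUE,
                                      prob = c(.4, .3, .2, .1)),
                               collapse = ""))
    pwm <- train_pwm(win, "donor", alpha = 1)
    cons <- pwm_consensus(pwm)
    smax <- score_site(pwm, cons)
    others <- replicate(50, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                                  collapse = ""))
    expect_true(all(vapply(others, function(w)
      score_site(pwm, w), 0) <= smax + 1e-12))
  }
})

test_that("PWM files round-trip", {
  pwm <- train_pwm(rep("CAGGTAAGT", 3), "donor", alpha = 0.5)
  f <- tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$site_kind, "donor")
  expect_equal(back$alpha, 0.5)
  expect_equal(unname(back$freq), unname(pwm$freq), tolerance = 1e-9)
})

test_that("branch-point search obeys the distance bounds", {
  gpad <- function(n) strrep("G", n)
  # CTAAC matches YUNAY; planted so the motif starts 30 nt upstream
  intron <- paste0(gpad(200), "CTAAC", gpad(25))
  hit <- find_branch_point(intron)
  expect_equal(hit$distance, 30L)
  expect_equal(hit$motif, "CTAAC")
  expect_false(hit$distal)
  # plant at 351 nt -> outside the hard bound
  far <- paste0(gpad(50), "CTAAC", gpad(346))
  expect_null(find_branch_point(far))
  at350 <- paste0(gpad(50), "CTAAC", gpad(345))
  expect_equal(find_branch_point(at350)$distance, 350L)
  expect_true(find_branch_point(at350)$distal)
  expect_null(find_branch_point(gpad(120)))
  # closest-to-3'SS tie-break among several matches
  two <- paste0(gpad(100), "CTAAC", gpad(40), "TTTAT", gpad(20))
  expect_equal(find_branch_point(two)$distance, 25L)
})

test_that("branch point and PPT match exhaustive oracles on random introns", {
  set.seed(7)
  for (i in 1:60) {
    intron <- paste(sample(c("A", "C", "G", "T"), sample(60:500, 1), TRUE),
                    collapse = "")
    bp <- find_branch_point(intron)
    obp <- oracle_bp(intron)
    expect_equal(bp$distance, obp, info = paste("intron", i))
    ppt <- find_ppt(intron)
    oppt <- oracle_ppt(intron)
    if (is.null(oppt)) {
      expect_null(ppt, info = paste("intron", i))
    } else {
      expect_equal(ppt, oppt, info = paste("intron", i))
    }
  }
})

test_that("PPT detection handles the stated boundary cases", {
  # 20 T's then CC spacer then AG terminus
  intron <- paste0(strrep("G", 100), strrep("T", 20), "CCAG")
  hit <- find_ppt(intron)
  expect_gte(hit$length, 20L)
  expect_null(find_ppt(paste(rep(c("A", "G"), 60), collapse = "")))
  # exactly 10 pyrimidines at the searchable 3' end: the run absorbs up to
  # four diluting purines before dropping below the 0.7 threshold
  # (oracle-derived: longest qualifying run is 14 nt at fraction 10/14)
  ten <- paste0(strrep("G", 80), strrep("C", 10), "GGAG")
  hit10 <- find_ppt(ten)
  expect_equal(hit10$length, 14L)
  expect_equal(hit10$pyrimidine_fraction, 10 / 14)
  expect_equal(hit10, oracle_ppt(ten))
  expect_null(find_ppt("TTTT"))  # shorter than any tract
})

test_that("SRE scanning counts overlapping matches and reports density", {
  # "TGCATGCATG" carries the 6-mer at offsets 0 AND 4 under the overlap
  # rule (verified against the position-loop oracle)
  res <- scan_sre("TGCATGCATG", motifs = c(UGCAUG = "TGCATG"))
  expect_equal(res$count, 2L)
  expect_equal(res$positions[[1]], oracle_scan("TGCATGCATG", "TGCATG"))
  res2 <- scan_sre("TTTTT", motifs = c(UUUU = "TTTT"))
  expect_equal(res2$count, 2L)
  expect_equal(res2$positions[[1]], c(0L, 1L))
  expect_equal(res2$density_per_100nt, 2 / 5 * 100)
  expect_equal(nrow(scan_sre("ACGT", motifs = character(0))), 0L)
  # RNA-alphabet motifs are accepted
  expect_equal(scan_sre("TCTCTCT", motifs = "UCUCU")$count, 2L)
  # oracle comparison across the default set on random sequence
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  res3 <- scan_sre(s)
  for (i in seq_len(nrow(res3)))
    expect_equal(res3$positions[[i]], oracle_scan(s, res3$kmer[i]))
})

test_that("default SRE cluster set holds exactly the six motifs", {
  expect_setequal(unname(default_sre_motifs()),
                  c("TCTCT", "TGCATG", "TGCT", "TGTGT", "TTTT", "AGGG"))
})

test_that("architecture features: lengths, ratio, GC, symmetry", {
  # internal exon of 100 nt flanked by introns of 400 and 600 nt
  g <- new_gene_model("g", list(
    new_transcript("t", "g", "c", "+",
                   data.frame(start = c(0L, 450L, 1150L),
                              end = c(50L, 550L, 1249L)))))
  arch <- architecture(g)
  mid <- arch[arch$start == 450L, ]
  expect_equal(mid$upstream_intron_length, 400)
  expect_equal(mid$downstream_intron_length, 600)
  expect_equal(mid$intron_to_exon_ratio, 5.0)
  expect_false(mid$symmetric)           # length 100
  expect_equal(arch$symmetric[3], TRUE) # length 99
  expect_true(is.na(arch$upstream_intron_length[1]))  # terminal exon
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_true(is.na(gc_content("GCNT")))
})

test_that("GC of a concatenation is the length-weighted mean of parts", {
  set.seed(5)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:50, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:50, 1), TRUE),
               collapse = "")
    expect_equal(gc_content(paste0(a, b)),
                 (gc_content(a) * nchar(a) + gc_content(b) * nchar(b)) /
                   (nchar(a) + nchar(b)))
  }
})

test_that("sequence features are strand-invariant under mirroring", {
  L <- nchar(wx$genome[["chrT"]])
  mg <- mirror_gene(wx$gene, L)
  mgen <- mirror_genome(wx$genome)
  a1 <- architecture(wx$gene, wx$genome)
  a2 <- architecture(mg, mgen)
  a2m <- a2[match(paste(L - a1$end, L - a1$start),
                  paste(a2$start, a2$end)), ]
  for (col in c("label", "exon_length", "upstream_intron_length",
                "downstream_intron_length", "intron_to_exon_ratio",
                "symmetric", "exon_gc", "upstream_boundary_gc",
                "downstream_boundary_gc"))
    expect_equal(a2m[[col]], a1[[col]], info = col, ignore_attr = TRUE)
})
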