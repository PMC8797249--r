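test_that("box motif finder handles consensus semantics", {
  # C box AUGAUGA (R = A), 30-nt spacer without U, D box CUGA
  seqs <- paste0("AACA", "AUGAUGA", strrep("AGCAGG", 5), "GGCCAAGGCCAA",
                 "CUGA", "CC")
  arr <- find_box_motifs(seqs)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$c_mm, 0L)  # R matched by A
  expect_equal(arr$c_start, 5L)

  # no D box -> empty
  expect_equal(nrow(find_box_motifs(paste0("AACA", "GUGAUGA",
                                           strrep("AGC", 20)))), 0L)

  # two C-box mismatches rejected at the default tolerance
  s2 <- paste0("AACA", "CUCAUGA", strrep("AGCAGG", 5), "GGCCAAGGCCAA",
               "CUGA", "CC")
  expect_equal(nrow(find_box_motifs(s2)), 0L)
  arr2 <- find_box_motifs(s2, guide_search_params(max_c_mismatches = 2L))
  expect_true(any(arr2$c_start == 5L & arr2$c_mm == 2L))

  expect_error(find_box_motifs("ACGUACGU"), "shorter")
})

test_that("duplex scoring follows the +5 rule and matches brute force", {
  ref <- random_ref(length = 200L, seed = 51L)
  # perfect guide against window [101, 112] targets residue 105
  window <- substr(ref$sequence, 101, 112)
  guide <- paste(rev(strsplit(chartr("ACGU", "UGCA", window), "")[[1]]),
                 collapse = "")
  hit <- score_guide_duplex(guide, ref)
  expect_equal(hit$window_start, 101L)
  expect_equal(hit$target_pos, 105L)
  expect_equal(hit$mismatches, 0L)

  expect_error(score_guide_duplex(strrep("A", 25), ref), "outside")

  # random guides: argmax window equals the exhaustive scan
  set.seed(52)
  small_ref <- random_ref(length = 40L, seed = 53L)
  n_checked <- 0L
  for (k in 1:60) {
    guide <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    want <- oracle_best_duplex(guide, small_ref$sequence)
    got <- score_guide_duplex(guide, small_ref)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_checked <- n_checked + 1L
      expect_equal(got$duplex_score, want$score)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
  # wobble accounting against the oracle on G/U-rich guides
  gu_ref <- rrna_reference("gu", strrep("GU", 20))
  for (k in 1:20) {
    guide <- paste(sample(c("G", "U", "A"), 12, TRUE), collapse = "")
    want <- oracle_best_duplex(guide, gu_ref$sequence)
    got <- score_guide_duplex(guide, gu_ref)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$duplex_score, want$score)
      expect_equal(got$window_start, want$start)
    }
  }
})

test_that("synthetic transcriptome round-trips through the scanner", {
  refs <- list(r18 = random_ref("r18", 600L, seed = 61L))
  targets <- data.frame(rrna = "r18", position = c(80L, 210L, 340L, 470L,
                                                   550L))
  gen <- generate_guide_transcriptome(refs, targets, n_decoys = 15L,
                                      seed = 62L)
  expect_length(gen$transcripts, 20L)
  expect_equal(nrow(gen$truth), 5L)

  # determinism: same seed, identical bytes
  gen2 <- generate_guide_transcriptome(refs, targets, n_decoys = 15L,
                                       seed = 62L)
  expect_identical(gen$transcripts, gen2$transcripts)

  # each guide transcript yields exactly one box arrangement at the
  # embedded coordinates
  for (i in seq_len(nrow(gen$truth))) {
    arr <- find_box_motifs(gen$transcripts[[gen$truth$transcript[i]]])
    expect_equal(nrow(arr), 1L)
    expect_equal(arr$c_start, 5L)
    expect_equal(arr$d_start, gen$truth$guide_end[i] + 1L)
  }

  cands <- scan_transcriptome(gen$transcripts, refs)
  expect_gte(nrow(cands), 5L)
  expect_true(all(!grepl("^decoy", cands$transcript)))

  # every embedded guide recovered with its intended +5-rule target
  assign <- assign_guides(cands, targets)
  expect_true(all(assign$assigned))
  expect_equal(assign$transcript,
               sprintf("sno_r18_%d", targets$position))

  # +5 rule consistency on every emitted candidate
  expect_equal(cands$target_pos, cands$window_start + 4L)

  # byte-determinism of the candidate table
  cands2 <- scan_transcriptome(gen$transcripts, refs)
  expect_identical(cands, cands2)

  # a site too close to the reference end is rejected by name
  expect_error(generate_guide_transcriptome(
    refs, data.frame(rrna = "r18", position = 2L), n_decoys = 0L, seed = 1L),
    "r18:2")
})

test_that("decoy windows keep distance from all antisense rRNA windows", {
  refs <- list(r18 = random_ref("r18", 400L, seed = 71L))
  gen <- generate_guide_transcriptome(
    refs, data.frame(rrna = "r18", position = 100L), n_decoys = 6L,
    seed = 72L)
  decoys <- gen$transcripts[grepl("^decoy", names(gen$transcripts))]
  ref_codes <- ribomethr:::.rna_int(refs$r18$sequence)
  for (d in decoys) {
    codes <- ribomethr:::.rna_int(d)
    for (s in seq_len(nchar(d) - 11L)) {
      st <- ribomethr:::.duplex_stats(codes[s:(s + 11L)], ref_codes)
      expect_gte(min(12L - st$matches), 3L)
    }
  }
})

test_that("assignment ranks by score, ortholog similarity, then position", {
  cands <- data.frame(
    transcript = c("t2", "t1", "t3"),
    span_start = c(1L, 1L, 1L), span_end = c(49L, 49L, 49L),
    guide_box = "D", guide_seq = "ACGUACGUACGU",
    rrna = "r", target_pos = 100L,
    score = c(18, 15, 18),
    snorna_seq = c("AACAGUGAUGAACGUACGUACGUCUGACC",   # close to ortholog
                   "GGGGGGGGGGGGGGGGGGGGGGGGGGGGG",
                   "UUUUUUUUUUUUUCCCCCCCCCCCCCCCC"))
  sites <- data.frame(rrna = "r", position = 100L)
  orth <- c(o1 = "AACAGUGAUGAACGUACGUACGUCUGACC")
  res <- assign_guides(cands, sites, orthologs = orth)
  expect_true(res$assigned)
  expect_equal(res$transcript, "t2")  # tie on 18 broken by ortholog score

  # without orthologs the (transcript, span) order breaks the tie
  res2 <- assign_guides(cands, sites)
  expect_equal(res2$transcript, "t2")  # t2 < t3 lexicographically

  # max-score rule
  res3 <- assign_guides(cands[1:2, ], sites)
  expect_equal(res3$transcript, "t2")

  # unassigned site reported, not an error
  res4 <- assign_guides(cands, data.frame(rrna = "r", position = 50L))
  expect_false(res4$assigned)
})

test_that("overlap aligner used for the tie-break matches the DP oracle", {
  set.seed(81)
  for (k in 1:15) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(6:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(6:12, 1), TRUE),
               collapse = "")
    got <- ribomethr:::.ortholog_alignment_score(a, setNames(b, "o"))
    want <- oracle_overlap_align(chartr("U", "T", a), chartr("U", "T", b))
    expect_equal(got, want)
  }
})
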