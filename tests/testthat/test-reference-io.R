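test_that("FASTA records parse, normalize and round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">18S some description", "ACGU", ">x", "acgt"), fa)
  refs <- read_rrna_fasta(fa)
  expect_named(refs, c("18S", "x"))
  expect_equal(refs$`18S`$sequence, "ACGU")
  expect_equal(refs$`18S`$length, 4L)
  expect_equal(refs$x$sequence, "ACGU")  # case and T/U normalization

  out <- withr::local_tempfile(fileext = ".fasta")
  write_rrna_fasta(refs, out)
  expect_equal(vapply(read_rrna_fasta(out), `[[`, "", "sequence"),
               vapply(refs, `[[`, "", "sequence"))
})

test_that("FASTA reader rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(read_rrna_fasta(fa))

  writeLines(c(">28S", "ACGU", ">28S", "ACGG"), fa)
  expect_error(read_rrna_fasta(fa), "duplicate")

  writeLines(c(">r1", "ACXGU"), fa)
  expect_error(read_rrna_fasta(fa), "position 3 of record 'r1'")
})

test_that("site catalog validates labels, ranges and reference agreement", {
  refs <- list(`28S` = rrna_reference("28S", strrep("A", 1000)),
               `18S` = rrna_reference("18S", strrep("U", 300)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(rrna = c("28S", "18S"), position = c(963L, 252L),
                       nucleotide = c("A", "U"),
                       previously_mapped = c(TRUE, FALSE),
                       low_dntp_validated = c(TRUE, FALSE),
                       human_counterpart = c("Am1322", "")),
            csv, row.names = FALSE)
  cat_ <- read_site_catalog(csv, refs)
  expect_s3_class(cat_, "site_catalog")
  expect_equal(cat_$label, c("Am963", "Um252"))
  expect_false(cat_$previously_mapped[2])

  # 1-based convention: position 0 rejected
  write.csv(data.frame(rrna = "28S", position = 0L, nucleotide = "A",
                       previously_mapped = TRUE, low_dntp_validated = FALSE,
                       human_counterpart = ""), csv, row.names = FALSE)
  expect_error(read_site_catalog(csv), "1-based")

  # nucleotide mismatch against the reference names the site
  write.csv(data.frame(rrna = "28S", position = 5L, nucleotide = "G",
                       previously_mapped = TRUE, low_dntp_validated = FALSE,
                       human_counterpart = ""), csv, row.names = FALSE)
  expect_error(read_site_catalog(csv, refs), "Gm5")

  # out-of-range position
  write.csv(data.frame(rrna = "18S", position = 301L, nucleotide = "U",
                       previously_mapped = TRUE, low_dntp_validated = FALSE,
                       human_counterpart = ""), csv, row.names = FALSE)
  expect_error(read_site_catalog(csv, refs), "beyond")
})

test_that("end-count tables densify, validate and round-trip", {
  refs <- list(r1 = rrna_reference("r1", strrep("A", 10)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rrna = "r1", position = c(1:6, 8:10),
                   five_prime_ends = c(5L, 0L, 2L, 1L, 0L, 3L, 4L, 0L, 1L),
                   three_prime_ends = c(0L, 1L, 1L, 2L, 0L, 0L, 5L, 2L, 0L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_end_counts(tsv, refs)$r1
  expect_length(prof$five_prime_ends, 10L)
  expect_equal(prof$five_prime_ends[7], 0L)  # densification
  expect_equal(prof$three_prime_ends[7], 0L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_end_counts(list(prof), out)
  back <- read_end_counts(out, refs)$r1
  expect_equal(back$five_prime_ends, prof$five_prime_ends)
  expect_equal(back$three_prime_ends, prof$three_prime_ends)

  df$five_prime_ends[1] <- -1L
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_end_counts(tsv, refs), "negative")

  df$five_prime_ends[1] <- 1L
  df$position[1] <- 11L
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_end_counts(tsv, refs), "exceeds")
})

test_that("SAM alignments are converted to end counts with filtering", {
  refs <- list(r1 = rrna_reference("r1", strrep("A", 60)))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:r1\tLN:60",
    # read spanning 5..24 (20M)
    "read1\t0\tr1\t5\t60\t20M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAA\t*",
    # secondary alignment: ignored
    "read2\t256\tr1\t10\t60\t20M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAA\t*",
    # unmapped: skipped
    "read3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*",
    # deletion consumes reference: 31..52
    "read4\t0\tr1\t31\t60\t10M2D10M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAA\t*"),
    sam)
  profs <- suppressMessages(parse_alignments(sam, refs))
  fp <- profs$r1$five_prime_ends
  tp <- profs$r1$three_prime_ends
  expect_equal(fp[5], 1L)
  expect_equal(tp[24], 1L)
  expect_equal(fp[10], 0L)          # secondary ignored
  expect_equal(fp[31], 1L)
  expect_equal(tp[52], 1L)          # CIGAR-aware 3' end
  expect_equal(sum(fp), 2L)

  # unknown reference name errors
  expect_error(suppressMessages(parse_alignments(sam, list(
    other = rrna_reference("other", strrep("A", 60))))), "other|r1")

  # zero usable alignments warn
  sam0 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:r1\tLN:60",
               "read3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"), sam0)
  expect_warning(suppressMessages(parse_alignments(sam0, refs)), "no usable")
})

test_that("BED export converts to 0-based half-open coordinates", {
  sites <- data.frame(rrna = "28S", position = 963L, label = "Am963",
                      mean_score = 0.912)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed_sites(sites, bed)
  row <- read.delim(bed, header = FALSE)
  expect_equal(row$V2, 962L)
  expect_equal(row$V3, 963L)
  expect_equal(row$V5, 912L)  # score x 1000
})

test_that("score matrices round-trip through CSV including missing cells", {
  scores <- matrix(c(0.5, NA, 0.123456, 0.9, 0.25, 1), nrow = 2,
                   dimnames = list(c("r1:Am5", "r1:Cm9"),
                                   c("s2_r1", "s2_r2", "s10_r1")))
  m <- structure(list(
    scores = scores,
    sites = data.frame(rrna = "r1", position = c(5L, 9L),
                       label = c("Am5", "Cm9")),
    samples = data.frame(sample_id = colnames(scores),
                         stage = c(2L, 2L, 10L), replicate = c(1L, 2L, 1L)),
    stage_means = NULL), class = "score_matrix")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_score_matrix(m, csv)
  back <- read_score_matrix(csv)
  expect_equal(back$scores, scores, tolerance = 1e-6)
  expect_true(is.na(back$scores["r1:Cm9", "s2_r1"]))
  expect_equal(back$samples$stage, c(2L, 2L, 10L))  # ids parsed back
  expect_equal(back$stage_means["r1:Cm9", "2"], 0.9)  # missing skipped
  expect_equal(back$stage_means["r1:Am5", "2"], mean(c(0.5, 0.123456)),
               tolerance = 1e-6)
})
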