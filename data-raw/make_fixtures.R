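# One-off builder of the packaged catalog fixtures (inst/extdata/*_synthetic*).
#
# The published repertoire: 103 2'-O-methylated rRNA positions (34 on 18S,
# 2 on 5.8S, 67 on 28S), 15 of them novel (1 on 18S, 14 on 28S), 23
# orthogonally validated by low-dNTP primer extension (10 novel + 13
# previously mapped, all on 28S), 10 sites constitutively hypomethylated,
# 12 hypomethylated only at stage 45 (3 on 18S, 1 on 5.8S, 8 on 28S), and
# one box C/D snoRNA assignment per site with 49 novel candidates.
#
# Every individually named residue and every count above is reproduced
# exactly. Everything that is not individually published — the reference
# sequences themselves, filler site positions, per-stage score values,
# human-counterpart labels of unnamed sites — is generated synthetically
# under a fixed seed, which is why all output filenames carry "_synthetic".
#
# Run from the package root:  Rscript data-raw/make_fixtures.R

set.seed(20260925)

parse_label <- function(x) {
  data.frame(nucleotide = substr(x, 1, 1),
             position = as.integer(sub("^[ACGU]m", "", x)))
}

named_site <- function(rrna, labels, previously_mapped = TRUE,
                       validated = FALSE, pattern = "robust",
                       human = NA_character_) {
  p <- parse_label(labels)
  data.frame(rrna = rrna, position = p$position, nucleotide = p$nucleotide,
             previously_mapped = previously_mapped,
             low_dntp_validated = validated, pattern = pattern,
             human_counterpart = human)
}

## ---- 18S (34 sites) -------------------------------------------------------
s18 <- rbind(
  named_site("18S", "Um252", previously_mapped = FALSE,
             pattern = "constitutive", human = ""),       # frog-specific
  named_site("18S", "Cm760", pattern = "constitutive"),
  named_site("18S", "Um1761", pattern = "constitutive"),
  named_site("18S", c("Um393", "Am477", "Am555"), pattern = "stage45")
)
# filler: robust, previously mapped positions
pool18 <- setdiff(seq(40L, 1780L, by = 5L), s18$position)
fill18 <- sort(sample(pool18, 34L - nrow(s18)))
s18 <- rbind(s18, data.frame(rrna = "18S", position = fill18,
                             nucleotide = sample(c("A", "C", "G", "U"),
                                                 length(fill18), TRUE),
                             previously_mapped = TRUE,
                             low_dntp_validated = FALSE, pattern = "robust",
                             human_counterpart = NA))

## ---- 5.8S (2 sites) -------------------------------------------------------
s58 <- rbind(
  named_site("5.8S", "Um14", pattern = "stage45"),
  named_site("5.8S", "Gm75", pattern = "robust")
)

## ---- 28S (67 sites) -------------------------------------------------------
novel_validated <- c("Am393", "Am395", "Am960", "Gm1286", "Am1886",
                     "Gm2398", "Gm2943", "Gm3050", "Gm3305", "Gm3501")
known_validated <- c("Am963", "Cm977", "Am2309", "Cm2326", "Um2359",
                     "Cm2383", "Am2869", "Am2875", "Am2911", "Am2936",
                     "Gm3534", "Gm3603", "Cm4013")
constitutive28 <- c("Am963", "Am1848", "Cm1850", "Gm2895", "Am2911",
                    "Am3018", "Cm3565")
stage45_28 <- c("Am393", "Cm1525", "Cm1907", "Am2337", "Cm3020", "Gm3534",
                "Am3680", "Gm3746")
not_conserved28 <- c("Gm432", "Cm1113", "Gm3534", "Cm4013")
novel_filler <- c("Cm1202", "Am2101", "Gm2642", "Um3888")  # synthetic names

named28 <- unique(c(novel_validated, known_validated, constitutive28,
                    stage45_28, not_conserved28))
s28 <- named_site("28S", named28)
s28$previously_mapped <- !(named28 %in% novel_validated)
s28$low_dntp_validated <- named28 %in% c(novel_validated, known_validated)
s28$pattern <- ifelse(named28 %in% constitutive28, "constitutive",
                      ifelse(named28 %in% stage45_28, "stage45", "robust"))
s28$human_counterpart <- ifelse(named28 %in% not_conserved28, "", NA)
s28 <- rbind(s28, named_site("28S", novel_filler, previously_mapped = FALSE))
pool28 <- setdiff(seq(60L, 4060L, by = 7L), s28$position)
fill28 <- sort(sample(pool28, 67L - nrow(s28)))
s28 <- rbind(s28, data.frame(rrna = "28S", position = fill28,
                             nucleotide = sample(c("A", "C", "G", "U"),
                                                 length(fill28), TRUE),
                             previously_mapped = TRUE,
                             low_dntp_validated = FALSE, pattern = "robust",
                             human_counterpart = NA))

catalog <- rbind(s18, s58, s28)
catalog <- catalog[order(match(catalog$rrna, c("18S", "5.8S", "28S")),
                         catalog$position), ]

# synthetic human-counterpart labels for conserved, unnamed sites
offset <- c(`18S` = 2L, `5.8S` = 0L, `28S` = 480L)
fill_hc <- is.na(catalog$human_counterpart)
catalog$human_counterpart[fill_hc] <-
  paste0(catalog$nucleotide[fill_hc], "m",
         catalog$position[fill_hc] + offset[catalog$rrna[fill_hc]])

stopifnot(nrow(catalog) == 103L,
          sum(catalog$rrna == "18S") == 34L,
          sum(catalog$rrna == "5.8S") == 2L,
          sum(catalog$rrna == "28S") == 67L,
          sum(!catalog$previously_mapped) == 15L,
          sum(!catalog$previously_mapped & catalog$rrna == "28S") == 14L,
          sum(catalog$low_dntp_validated) == 23L,
          sum(catalog$low_dntp_validated & !catalog$previously_mapped) == 10L,
          sum(catalog$pattern == "constitutive") == 10L,
          sum(catalog$pattern == "stage45") == 12L,
          !anyDuplicated(paste(catalog$rrna, catalog$position)))

## ---- synthetic reference sequences with catalog bases planted -------------
lens <- c(`18S` = 1826L, `5.8S` = 162L, `28S` = 4115L)
seqs <- vapply(names(lens), function(nm) {
  s <- sample(c("A", "C", "G", "U"), lens[[nm]], replace = TRUE)
  sub <- catalog[catalog$rrna == nm, ]
  s[sub$position] <- sub$nucleotide
  paste(s, collapse = "")
}, "")

## ---- per-stage mean scores consistent with the pattern classes ------------
stages <- c(2L, 10L, 16L, 23L, 32L, 45L)
n <- nrow(catalog)
scores <- matrix(NA_real_, n, length(stages))
for (k in seq_along(stages)) {
  scores[, k] <- round(runif(n, 0.85, 0.97), 3)                  # robust
  con <- catalog$pattern == "constitutive"
  scores[con, k] <- round(runif(sum(con), 0.40, 0.65), 3)
  s45 <- catalog$pattern == "stage45"
  scores[s45, k] <- if (stages[k] == 45L) {
    round(runif(sum(s45), 0.45, 0.65), 3)
  } else round(runif(sum(s45), 0.85, 0.95), 3)
}
colnames(scores) <- paste0("stage_", stages)

## ---- snoRNA assignments: one guide per site, 49 novel candidates ----------
novel_sno <- rep(FALSE, n)
novel_sno[!catalog$previously_mapped] <- TRUE                    # 15
novel_sno[sample(which(catalog$previously_mapped), 34L)] <- TRUE # + 34 = 49
sno <- data.frame(
  rrna = catalog$rrna, position = catalog$position,
  label = paste0(catalog$nucleotide, "m", catalog$position),
  snorna_id = sprintf("XLsno-CD-%03d", seq_len(n)),
  rfam_family = ifelse(novel_sno, "",
                       sprintf("SNORD%03d", 100L + cumsum(!novel_sno))))
stopifnot(sum(sno$rfam_family == "") == 49L)

## ---- write ----------------------------------------------------------------
out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fa <- file(file.path(out, "xl_rrna_synthetic.fasta"), "w")
for (nm in names(seqs)) {
  writeLines(paste0(">", nm, " synthetic stand-in sequence"), fa)
  starts <- seq(1L, nchar(seqs[[nm]]), by = 70L)
  writeLines(substring(seqs[[nm]], starts,
                       pmin(starts + 69L, nchar(seqs[[nm]]))), fa)
}
close(fa)

write.csv(catalog[, c("rrna", "position", "nucleotide", "previously_mapped",
                      "low_dntp_validated", "human_counterpart")],
          file.path(out, "xl_site_catalog_synthetic.csv"), row.names = FALSE)

write.csv(cbind(catalog[, c("rrna", "position")],
                label = paste0(catalog$nucleotide, "m", catalog$position),
                as.data.frame(scores)),
          file.path(out, "xl_stage_scores_synthetic.csv"), row.names = FALSE)

write.csv(sno, file.path(out, "xl_snorna_assignments_synthetic.csv"),
          row.names = FALSE)

cat("fixtures written to", out, "\n")
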