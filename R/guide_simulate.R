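#' Generate a synthetic guide-bearing transcriptome
#'
#' Emulates the input of a transcriptome-wide snoRNA screen. For every
#' target site one transcript carries a canonical box C/D snoRNA shaped like
#' a guide-finder report: four leading nucleotides, the C box (GUGAUGA), a
#' 20-nt spacer, a 12-nt guide exactly antisense to the rRNA window dictated
#' by the +5 rule, the D box (CUGA), and two trailing nucleotides. The
#' spacer is built without U (so no spurious C- or D-box motif can arise in
#' it) and its 3'-terminal nucleotides are chosen to mismatch any leftward
#' extension of the guide/rRNA duplex, making the embedded 12-mer the unique
#' best duplex and the +5-rule target recovery exact.
#'
#' Decoy transcripts are random sequences post-processed so that every
#' 12-nt window is at Hamming distance >= 3 from the antisense of every
#' 12-nt window of every rRNA (i.e. at most 9 Watson-Crick pairs in any
#' 12-mer duplex); together with the vanishing probability of a chance
#' C-box/D-box arrangement, decoys yield no guide candidate.
#'
#' @param refs named list of [rrna_reference].
#' @param target_sites data frame with `rrna`, `position` (catalog subset).
#' @param n_decoys number of decoy transcripts (default 50).
#' @param seed RNG seed.
#' @param decoy_len decoy length (default 60).
#' @param params the [guide_search_params] the transcriptome is verified
#'   against: each guide transcript is re-scanned after construction and
#'   its spacer resampled in the rare case a chance longer duplex elsewhere
#'   on the references would outscore the embedded guide.
#' @return list with `transcripts` (named character vector) and `truth`
#'   (data frame: transcript, guide_start, guide_end, rrna, target).
#' @export
generate_guide_transcriptome <- function(refs, target_sites, n_decoys = 50L,
                                         seed = NULL, decoy_len = 60L,
                                         params = guide_search_params()) {
  spacer_len <- 20L
  lead <- "AACA"; cbox <- "GUGAUGA"; dbox <- "CUGA"; trail <- "CC"
  with_seed(seed, {
    tx <- character(0)
    truth <- list()
    for (i in seq_len(nrow(target_sites))) {
      nm <- target_sites$rrna[i]
      pos <- as.integer(target_sites$position[i])
      ref <- refs[[nm]]
      if (is.null(ref)) stop("target rRNA '", nm, "' not among references",
                             call. = FALSE)
      if (pos - 4L < 1L || pos + 7L > ref$length) {
        stop("site ", nm, ":", pos,
             " too close to a reference end to host a 12-nt guide window",
             call. = FALSE)
      }
      window <- substr(ref$sequence, pos - 4L, pos + 7L)
      guide <- .revcomp_rna(window)
      name <- sprintf("sno_%s_%d", nm, pos)
      seqs <- NULL
      for (try in seq_len(50L)) {
        # spacer: U-free; last 9 nt each mismatch the corresponding residue
        # of a leftward duplex extension (rRNA positions pos-5 .. pos-13)
        spacer <- sample(c("A", "C", "G"), spacer_len, replace = TRUE)
        for (k in seq_len(9L)) {
          rpos <- pos - 4L - k
          r <- if (rpos >= 1L) substr(ref$sequence, rpos, rpos) else "A"
          allowed <- switch(r,
                            A = c("A", "C", "G"),  # only U pairs A
                            C = c("A", "C"),       # G pairs C
                            G = c("A", "G"),       # C pairs, U wobbles
                            U = "C")               # A pairs, G wobbles
          spacer[spacer_len - k + 1L] <- if (length(allowed) > 1L)
            sample(allowed, 1L) else allowed
        }
        cand_tx <- paste0(lead, cbox, paste(spacer, collapse = ""),
                          guide, dbox, trail)
        # verify: the best D-box duplex of the finished transcript must be
        # the embedded guide (a chance near-antisense repeat elsewhere can
        # otherwise recruit spacer nucleotides into a longer duplex)
        got <- scan_transcriptome(stats::setNames(cand_tx, name), refs,
                                  params)
        dbox_hit <- got[got$guide_box == "D", , drop = FALSE]
        if (nrow(dbox_hit) == 1L && dbox_hit$rrna == nm &&
            dbox_hit$target_pos == pos) {
          seqs <- cand_tx
          break
        }
      }
      if (is.null(seqs)) {
        stop("could not embed an unambiguous guide for ", nm, ":", pos,
             call. = FALSE)
      }
      tx[name] <- seqs
      gstart <- nchar(lead) + nchar(cbox) + spacer_len + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        transcript = name, guide_start = gstart, guide_end = gstart + 11L,
        rrna = nm, target = pos)
    }
    ref_anti <- lapply(refs, function(r) .rna_int(.revcomp_rna(r$sequence)))
    for (k in seq_len(n_decoys)) {
      name <- sprintf("decoy_%03d", k)
      tx[name] <- .make_decoy(decoy_len, ref_anti)
    }
    list(transcripts = tx,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(transcript = character(0), guide_start = integer(0),
                      guide_end = integer(0), rrna = character(0),
                      target = integer(0)))
  })
}

# Greedy construction of a sequence in which every 12-nt window keeps
# Hamming distance >= 3 from every antisense rRNA 12-mer. The antisense
# 12-mers of a reference are exactly the 12-nt substrings of its reverse
# complement (ref_anti), so the constraint is a k-mismatch substring
# exclusion. Positions are chosen left to right: the distance contributed
# by the 11 already-fixed window positions is computed once (vectorized
# over all reference windows), which letters would close the gap to < 3 is
# then read off, and a letter keeping every window at distance >= 3 is
# sampled. When no letter works (a reference window is already within
# distance 1 of the 11-mer prefix), the walk backtracks a few positions.
.make_decoy <- function(len, ref_anti) {
  codes <- integer(len)
  p <- 1L
  guard <- 0L
  while (p <= len) {
    if (p < 12L) {
      codes[p] <- sample.int(4L, 1L)
      p <- p + 1L
      next
    }
    ok <- rep(TRUE, 4L)
    for (B in ref_anti) {
      nw <- length(B) - 11L
      if (nw < 1L) next
      d11 <- integer(nw)
      for (k in 1:11) {
        d11 <- d11 + as.integer(B[k:(k + nw - 1L)] != codes[p - 12L + k])
      }
      close <- which(d11 <= 2L)
      if (!length(close)) next
      if (any(d11[close] <= 1L)) { ok[] <- FALSE; break }
      ok[unique(B[close + 11L])] <- FALSE  # matching last letter gives d = 2
    }
    if (!any(ok)) {
      guard <- guard + 1L
      if (guard > 1000L) {
        stop("failed to construct a decoy transcript", call. = FALSE)
      }
      p <- max(p - 6L, 1L)
      next
    }
    avail <- which(ok)
    codes[p] <- if (length(avail) == 1L) avail else sample(avail, 1L)
    p <- p + 1L
  }
  .int_rna(codes)
}
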