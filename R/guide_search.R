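#' Parameters of the box C/D guide search
#'
#' A deterministic motif-plus-duplex model of a methylation-guide snoRNA: a
#' C box (consensus RUGAUGA, R = A/G) upstream of an exact D box (CUGA),
#' with an optional internal D' box, and an antisense guide element
#' immediately 5' of the D (or D') box that base-pairs with the rRNA. The
#' rRNA residue paired with the 5th guide nucleotide counted upstream from
#' the box receives the methyl group (the "+5 rule").
#'
#' Duplex scoring: Watson-Crick pair +1, G.U wobble `wobble_weight`,
#' mismatch -2; windows with more than `max_duplex_mismatches` mismatches
#' are discarded. Candidate score = duplex score + box bonuses (C +5, D +3,
#' D' +2) - 2 per C-box mismatch; candidates below `min_report_score` are
#' dropped.
#'
#' @param max_c_mismatches mismatches tolerated against RUGAUGA (default 1).
#' @param min_guide_len,max_guide_len guide length bounds (defaults 10, 21).
#' @param min_box_sep,max_box_sep C-to-D box separation bounds in nt
#'   (defaults 30, 200).
#' @param max_duplex_mismatches per-duplex mismatch ceiling (default 1).
#' @param wobble_weight score of a G.U pair (default 0.5).
#' @param c_box_bonus,d_box_bonus,d_prime_bonus box bonuses (5, 3, 2).
#' @param min_report_score reporting threshold (default 12).
#' @return list of class `guide_search_params`.
#' @export
guide_search_params <- function(max_c_mismatches = 1L,
                                min_guide_len = 10L, max_guide_len = 21L,
                                min_box_sep = 30L, max_box_sep = 200L,
                                max_duplex_mismatches = 1L,
                                wobble_weight = 0.5,
                                c_box_bonus = 5, d_box_bonus = 3,
                                d_prime_bonus = 2,
                                min_report_score = 12) {
  if (min_guide_len > max_guide_len) {
    stop("min_guide_len must not exceed max_guide_len", call. = FALSE)
  }
  structure(list(max_c_mismatches = as.integer(max_c_mismatches),
                 min_guide_len = as.integer(min_guide_len),
                 max_guide_len = as.integer(max_guide_len),
                 min_box_sep = as.integer(min_box_sep),
                 max_box_sep = as.integer(max_box_sep),
                 max_duplex_mismatches = as.integer(max_duplex_mismatches),
                 wobble_weight = wobble_weight,
                 c_box_bonus = c_box_bonus, d_box_bonus = d_box_bonus,
                 d_prime_bonus = d_prime_bonus,
                 min_report_score = min_report_score),
            class = "guide_search_params")
}

# mismatch count of a length-7 window against RUGAUGA, vectorized over starts
.c_box_mismatches <- function(chars, starts) {
  consensus <- c(NA, "U", "G", "A", "U", "G", "A")  # position 1 is R
  mm <- integer(length(starts))
  r1 <- chars[starts]
  mm <- mm + as.integer(!(r1 == "A" | r1 == "G"))
  for (k in 2:7) mm <- mm + as.integer(chars[starts + k - 1L] != consensus[k])
  mm
}

#' Find box C/D arrangements in a transcript
#'
#' Enumerates all (C box, D box) arrangements: a C box (<=
#' `max_c_mismatches` vs RUGAUGA) upstream of an exact CUGA D box, with a
#' box separation (nt strictly between C-box end and D-box start) within
#' `[min_box_sep, max_box_sep]`. For each arrangement the best internal D'
#' box (CUGA with <= 1 mismatch, fewest mismatches then leftmost) is
#' annotated when present.
#'
#' @param sequence transcript sequence (length >= 30).
#' @param params a [guide_search_params].
#' @return data frame with one row per arrangement: `c_start`, `c_seq`,
#'   `c_mm`, `d_start`, `sep`, `d_prime_start`, `d_prime_seq`, `d_prime_mm`
#'   (NA when absent). Zero rows when no arrangement exists.
#' @export
find_box_motifs <- function(sequence, params = guide_search_params()) {
  s <- .norm_rna(sequence, "transcript")
  n <- nchar(s)
  if (n < 30L) stop("transcript shorter than 30 nt", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  empty <- data.frame(c_start = integer(0), c_seq = character(0),
                      c_mm = integer(0), d_start = integer(0),
                      sep = integer(0), d_prime_start = integer(0),
                      d_prime_seq = character(0), d_prime_mm = integer(0))
  d_starts <- which(vapply(seq_len(max(n - 3L, 0L)), function(i) {
    substr(s, i, i + 3L) == "CUGA"
  }, logical(1)))
  if (!length(d_starts)) return(empty)
  c_starts <- seq_len(n - 6L)
  c_mm <- .c_box_mismatches(chars, c_starts)
  c_keep <- c_starts[c_mm <= params$max_c_mismatches]
  if (!length(c_keep)) return(empty)
  rows <- list()
  for (d in d_starts) {
    for (cs in c_keep) {
      sep <- d - (cs + 6L) - 1L
      if (sep < params$min_box_sep || sep > params$max_box_sep) next
      # best internal D'-like box between the C and D boxes
      dp_start <- NA_integer_; dp_mm <- NA_integer_; dp_seq <- NA_character_
      region <- if (d - 5L >= cs + 7L) seq(cs + 7L, d - 5L) else integer(0)
      if (length(region)) {
        mm <- vapply(region, function(i) {
          sum(chars[i:(i + 3L)] != c("C", "U", "G", "A"))
        }, integer(1))
        ok <- which(mm <= 1L & region + 3L < d)
        if (length(ok)) {
          best <- ok[order(mm[ok], region[ok])][1]
          dp_start <- region[best]; dp_mm <- mm[best]
          dp_seq <- substr(s, dp_start, dp_start + 3L)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        c_start = cs, c_seq = substr(s, cs, cs + 6L),
        c_mm = c_mm[match(cs, c_starts)], d_start = d, sep = sep,
        d_prime_start = dp_start, d_prime_seq = dp_seq, d_prime_mm = dp_mm)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$c_start, out$d_start), , drop = FALSE]
}

# pairing statistics of a guide (5'->3') against every same-length rRNA
# window, antiparallel: guide position k pairs window position n-k+1.
# Returns per-window matches, wobbles, mismatches.
.duplex_stats <- function(guide_codes, ref_codes) {
  n <- length(guide_codes)
  L <- length(ref_codes)
  nw <- L - n + 1L
  if (nw < 1L) return(NULL)
  # parallel comparison against the reverse complement of the guide
  comp <- c(4L, 3L, 2L, 1L)                    # A<->U, C<->G
  q <- rev(comp[guide_codes])                  # q[j] pairs window pos j by WC
  match <- integer(nw); wob <- integer(nw)
  for (j in seq_len(n)) {
    rj <- ref_codes[j:(j + nw - 1L)]
    match <- match + as.integer(rj == q[j])
    # wobble: guide G with rRNA U (q[j] == C) or guide U with rRNA G (q[j] == A)
    if (q[j] == 2L) wob <- wob + as.integer(rj == 4L)
    if (q[j] == 1L) wob <- wob + as.integer(rj == 3L)
  }
  list(matches = match, wobbles = wob, mismatches = n - match - wob)
}

#' Score a guide element against an rRNA and apply the +5 rule
#'
#' Scans every rRNA window of the guide's length for antiparallel pairing
#' (Watson-Crick +1, G.U wobble `wobble_weight`, mismatch -2); windows with
#' more than `max_duplex_mismatches` mismatches are discarded. For the best
#' window, the predicted target is the rRNA residue paired with the guide
#' nucleotide 5 positions upstream of the abutting box (box-adjacent guide
#' nucleotide = position 1), i.e. the 5th window position from its 5' end.
#'
#' @param guide guide sequence, 5'->3', its 3' end abutting the box.
#' @param ref an [rrna_reference].
#' @param params a [guide_search_params].
#' @return `NULL` when no window passes, else a list with `window_start`,
#'   `window_end`, `matches`, `wobbles`, `mismatches`, `duplex_score`,
#'   `target_pos`.
#' @export
score_guide_duplex <- function(guide, ref, params = guide_search_params()) {
  guide <- .norm_rna(guide, "guide")
  n <- nchar(guide)
  if (n < params$min_guide_len || n > params$max_guide_len) {
    stop("guide length ", n, " outside [", params$min_guide_len, ", ",
         params$max_guide_len, "]", call. = FALSE)
  }
  st <- .duplex_stats(.rna_int(guide), .rna_int(ref$sequence))
  if (is.null(st)) return(NULL)
  score <- st$matches + params$wobble_weight * st$wobbles - 2 * st$mismatches
  ok <- which(st$mismatches <= params$max_duplex_mismatches)
  if (!length(ok)) return(NULL)
  best <- ok[order(-score[ok], ok)][1]
  list(window_start = best, window_end = best + n - 1L,
       matches = st$matches[best], wobbles = st$wobbles[best],
       mismatches = st$mismatches[best], duplex_score = score[best],
       target_pos = best + 4L)
}

#' Scan transcripts for box C/D snoRNA candidates
#'
#' Composes [find_box_motifs()] with [score_guide_duplex()]: for every
#' (C box, D box) arrangement and for the D box (and D' box when present),
#' guides of every admissible length ending immediately 5' of the box are
#' scored against every rRNA; the best duplex (highest duplex score, then
#' longer guide, then leftmost window) defines the candidate. Candidate
#' score = duplex score + box bonuses - 2 per C-box mismatch; candidates
#' below `min_report_score` are dropped. Output rows are ordered by
#' (transcript, span start, box) and are byte-deterministic.
#'
#' @param transcripts named character vector (or named list) of transcript
#'   sequences.
#' @param refs named list of [rrna_reference].
#' @param params a [guide_search_params].
#' @return data frame of class `snorna_candidates`, one row per candidate.
#' @export
scan_transcriptome <- function(transcripts, refs,
                               params = guide_search_params()) {
  transcripts <- unlist(transcripts)
  rows <- list()
  for (tx in names(transcripts)) {
    s <- .norm_rna(transcripts[[tx]], sprintf("transcript '%s'", tx))
    n <- nchar(s)
    arr <- tryCatch(find_box_motifs(s, params), error = function(e) NULL)
    if (is.null(arr) || nrow(arr) == 0L) next
    for (a in seq_len(nrow(arr))) {
      boxes <- data.frame(box = "D", box_start = arr$d_start[a])
      if (!is.na(arr$d_prime_start[a])) {
        boxes <- rbind(boxes, data.frame(box = "Dprime",
                                         box_start = arr$d_prime_start[a]))
      }
      has_dprime <- !is.na(arr$d_prime_start[a])
      for (b in seq_len(nrow(boxes))) {
        box_start <- boxes$box_start[b]
        guide_end <- box_start - 1L
        best <- NULL
        for (g in seq(params$min_guide_len, params$max_guide_len)) {
          guide_start <- guide_end - g + 1L
          if (guide_start <= arr$c_start[a] + 6L) next
          guide <- substr(s, guide_start, guide_end)
          for (nm in names(refs)) {
            hit <- score_guide_duplex(guide, refs[[nm]], params)
            if (is.null(hit)) next
            better <- is.null(best) ||
              hit$duplex_score > best$duplex_score ||
              (hit$duplex_score == best$duplex_score && g > best$guide_len) ||
              (hit$duplex_score == best$duplex_score && g == best$guide_len &&
                 hit$window_start < best$window_start)
            if (better) {
              best <- c(hit, list(guide_len = g, guide_start = guide_start,
                                  guide_seq = guide, rrna = nm))
            }
          }
        }
        if (is.null(best)) next
        total <- best$duplex_score + params$c_box_bonus + params$d_box_bonus +
          (if (has_dprime) params$d_prime_bonus else 0) -
          2 * arr$c_mm[a]
        if (total < params$min_report_score) next
        span_start <- max(arr$c_start[a] - 4L, 1L)
        span_end <- min(arr$d_start[a] + 3L + 2L, n)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = tx, span_start = span_start, span_end = span_end,
          c_start = arr$c_start[a], c_seq = arr$c_seq[a], c_mm = arr$c_mm[a],
          d_start = arr$d_start[a],
          d_prime_start = arr$d_prime_start[a],
          guide_box = boxes$box[b],
          guide_start = best$guide_start,
          guide_end = best$guide_start + best$guide_len - 1L,
          guide_seq = best$guide_seq,
          rrna = best$rrna,
          window_start = best$window_start, window_end = best$window_end,
          target_pos = best$target_pos,
          matches = best$matches, wobbles = best$wobbles,
          mismatches = best$mismatches,
          duplex_score = best$duplex_score, score = total,
          snorna_seq = substr(s, span_start, span_end))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    out <- out[order(out$transcript, out$span_start, out$guide_box), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("snorna_candidates", "data.frame")
  out
}

#' @export
print.snorna_candidates <- function(x, ...) {
  cat(sprintf("<snorna_candidates> %d candidate(s)\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(utils::head(x[, c("transcript", "guide_box", "rrna",
                                       "target_pos", "score")], 10))
  }
  invisible(x)
}

# overlap (free end gaps) pairwise alignment score: match +1, mismatch -1,
# gap -2. RNA is mapped to DNA for the aligner's substitution matrix.
.ortholog_alignment_score <- function(seq, orthologs) {
  if (is.null(orthologs) || length(orthologs) == 0L) return(NA_real_)
  to_dna <- function(x) Biostrings::DNAString(chartr("U", "T", x))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  max(vapply(orthologs, function(o) {
    Biostrings::pairwiseAlignment(to_dna(seq), to_dna(o), type = "overlap",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = 2,
                                  scoreOnly = TRUE)
  }, numeric(1)))
}

#' Assign the best snoRNA candidate to each methylated site
#'
#' For every site, among candidates whose +5-rule target matches the site,
#' the highest-scoring one is chosen; ties are broken by the best global
#' pairwise alignment score (match +1, mismatch -1, gap -2, free end gaps)
#' against any member of the ortholog set, then by (transcript, span start)
#' lexicographic order. Sites with no candidate are reported unassigned.
#'
#' @param candidates output of [scan_transcriptome()].
#' @param sites data frame with `rrna`, `position` (and optionally `label`).
#' @param orthologs optional named character vector of reference snoRNA
#'   sequences (e.g. from a related species) used for the tie-break and the
#'   reported similarity score.
#' @param params a [guide_search_params].
#' @return data frame of class `guide_assignments`, one row per site, with
#'   the chosen candidate's fields, its `ortholog_score`, and `assigned`.
#' @export
assign_guides <- function(candidates, sites, orthologs = NULL,
                          params = guide_search_params()) {
  label <- if ("label" %in% names(sites)) sites$label else
    as.character(sites$position)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    hit <- candidates[candidates$rrna == sites$rrna[i] &
                        candidates$target_pos == sites$position[i], ,
                      drop = FALSE]
    if (nrow(hit) == 0L) {
      rows[[i]] <- data.frame(rrna = sites$rrna[i],
                              position = sites$position[i],
                              label = label[i], assigned = FALSE,
                              transcript = NA_character_,
                              span_start = NA_integer_, span_end = NA_integer_,
                              guide_box = NA_character_,
                              guide_seq = NA_character_,
                              score = NA_real_, ortholog_score = NA_real_,
                              snorna_seq = NA_character_)
      next
    }
    hit$ortholog_score <- vapply(hit$snorna_seq, .ortholog_alignment_score,
                                 numeric(1), orthologs = orthologs)
    ord <- order(-hit$score,
                 -ifelse(is.na(hit$ortholog_score), -Inf, hit$ortholog_score),
                 hit$transcript, hit$span_start)
    best <- hit[ord[1], ]
    rows[[i]] <- data.frame(rrna = sites$rrna[i], position = sites$position[i],
                            label = label[i], assigned = TRUE,
                            transcript = best$transcript,
                            span_start = best$span_start,
                            span_end = best$span_end,
                            guide_box = best$guide_box,
                            guide_seq = best$guide_seq,
                            score = best$score,
                            ortholog_score = best$ortholog_score,
                            snorna_seq = best$snorna_seq)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("guide_assignments", "data.frame")
  out
}

#' @export
print.guide_assignments <- function(x, ...) {
  cat(sprintf("<guide_assignments> %d site(s), %d assigned, %d unassigned\n",
              nrow(x), sum(x$assigned), sum(!x$assigned)))
  invisible(x)
}
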