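# Independent reference implementations used to cross-check the package.

# direct loop-based protection score (mirrors the published formula, written
# independently of compute_score_track's vectorized path)
oracle_score_track <- function(fp, tp, l = 6L, min_neighbors = 3L,
                               min_local_ends = 10, taper = TRUE,
                               clamp = TRUE) {
  L <- length(fp)
  nb <- L - 1L
  n <- fp[2:L] + tp[1:nb]
  w <- if (taper) (l + 1 - seq_len(l)) / l else rep(1, l)
  score <- rep(NA_real_, L)
  for (i in seq_len(nb)) {
    lj <- which(i - seq_len(l) >= 1L)
    rj <- which(i + seq_len(l) <= nb)
    if (length(lj) < min_neighbors || length(rj) < min_neighbors) next
    a_l <- sum(w[lj] * n[i - lj]) / sum(w[lj])
    a_r <- sum(w[rj] * n[i + rj]) / sum(w[rj])
    b <- (a_l + a_r) / 2
    if (!is.finite(b) || b < min_local_ends) next
    s <- 1 - n[i] / b
    if (clamp) s <- min(max(s, 0), 1)
    score[i] <- s
  }
  score
}

# exhaustive antiparallel duplex scan (per-window classification by explicit
# character pairing rules)
oracle_best_duplex <- function(guide, refseq, wobble_weight = 0.5,
                               max_mm = 1L) {
  pair_class <- function(g, r) {
    if ((g == "A" && r == "U") || (g == "U" && r == "A") ||
        (g == "G" && r == "C") || (g == "C" && r == "G")) return("wc")
    if ((g == "G" && r == "U") || (g == "U" && r == "G")) return("wob")
    "mm"
  }
  n <- nchar(guide)
  L <- nchar(refseq)
  best <- NULL
  for (a in seq_len(L - n + 1L)) {
    win <- substr(refseq, a, a + n - 1L)
    cls <- vapply(seq_len(n), function(k) {
      pair_class(substr(guide, k, k), substr(win, n - k + 1L, n - k + 1L))
    }, "")
    mm <- sum(cls == "mm")
    if (mm > max_mm) next
    sc <- sum(cls == "wc") + wobble_weight * sum(cls == "wob") - 2 * mm
    if (is.null(best) || sc > best$score) {
      best <- list(start = a, score = sc, mismatches = mm)
    }
  }
  best
}

# free-end-gap global alignment score by explicit dynamic programming
oracle_overlap_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(
        M[i, j] + if (a[i] == b[j]) match else mismatch,
        M[i, j + 1L] + gap,
        M[i + 1L, j] + gap)
    }
  }
  max(M[n + 1L, ], M[, m + 1L])
}

# small random reference for unit tests
random_ref <- function(name = "rx", length = 300L, seed = 1L) {
  rrna_reference(name, withr_seed_sample(length, seed))
}

withr_seed_sample <- function(length, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = "")
}

# bond-count profile helper: builds an end-count profile whose bond end
# counts are as requested (split between 5' and 3' ends)
profile_from_bond_counts <- function(n, rrna = "x") {
  L <- length(n) + 1L
  fp <- integer(L); tp <- integer(L)
  fp[2:L] <- n %/% 2L
  tp[1:(L - 1L)] <- n - n %/% 2L
  end_count_profile(rrna, fp, tp)
}
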