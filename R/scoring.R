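#' Scoring parameters for the protection score
#'
#' The per-position methylation score compares the end count at a bond with
#' a weighted local baseline. `window` flanking bonds on each side enter the
#' baseline; with the default `"linear-taper"` scheme the weight of the
#' neighbor at offset `j` is `(window + 1 - j) / window`, so close neighbors
#' dominate; `"uniform"` weights all flanks equally.
#'
#' @param window number of flanking bonds per side (default 6).
#' @param weights `"linear-taper"` or `"uniform"`.
#' @param min_neighbors minimum usable flanking bonds per side for a score
#'   to be reported (default 3).
#' @param min_local_ends minimum local baseline (expected end count) below
#'   which the score is reported missing (default 10).
#' @param clamp clamp scores into \[0, 1\] (default TRUE).
#' @param ends `"both"` sums 5' ends at `i + 1` and 3' ends at `i` (both
#'   read out cleavage of bond `i`); `"five_prime"` uses 5' ends only.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(window = 6L,
                           weights = c("linear-taper", "uniform"),
                           min_neighbors = 3L,
                           min_local_ends = 10,
                           clamp = TRUE,
                           ends = c("both", "five_prime")) {
  weights <- match.arg(weights)
  ends <- match.arg(ends)
  window <- as.integer(window)
  min_neighbors <- as.integer(min_neighbors)
  if (window < 1L || min_neighbors < 1L || min_neighbors > window) {
    stop("need window >= min_neighbors >= 1", call. = FALSE)
  }
  structure(list(window = window, weights = weights,
                 min_neighbors = min_neighbors,
                 min_local_ends = min_local_ends,
                 clamp = clamp, ends = ends),
            class = "scoring_params")
}

.weight_vector <- function(params) {
  j <- seq_len(params$window)
  if (params$weights == "linear-taper") (params$window + 1 - j) / params$window
  else rep(1, params$window)
}

#' End count at the bond 3' of a residue
#'
#' Cleavage of bond `i` (joining residues `i` and `i + 1`) produces
#' fragments with a 3' end at `i` and fragments with a 5' end at `i + 1`;
#' both read out the same bond, so its end count is
#' `five_prime_ends[i + 1] + three_prime_ends[i]`.
#'
#' @param profile an [end_count_profile].
#' @param i bond index (vectorized), `1 <= i <= L - 1`.
#' @param ends `"both"` (default) or `"five_prime"`.
#' @return integer vector of bond end counts.
#' @export
bond_end_count <- function(profile, i, ends = "both") {
  L <- length(profile$five_prime_ends)
  i <- as.integer(i)
  if (any(i < 1L) || any(i >= L)) {
    stop("bond index must lie in 1..L-1 (residue L has no 3'-adjacent bond)",
         call. = FALSE)
  }
  n <- profile$five_prime_ends[i + 1L]
  if (ends == "both") n <- n + profile$three_prime_ends[i]
  n
}

#' Compute a per-position protection-score track
#'
#' For each bond `i`, the weighted mean of the `window` left-flanking bond
#' end counts (`A_L`) and of the right-flanking ones (`A_R`) — flanks
#' outside `1..L-1` are excluded and the weights renormalized — define the
#' local baseline `B_i = (A_L + A_R) / 2`, and the methylation score is
#' `1 - n_i / B_i`, clamped into \[0, 1\]. A fully cleavable (unmethylated)
#' bond scores ~0; a fully protected bond scores 1. The score is missing
#' (`NA`) at position `L`, wherever a side has fewer than `min_neighbors`
#' usable flanks, and wherever `B_i < min_local_ends`.
#'
#' @param profile an [end_count_profile].
#' @param params a [scoring_params] object.
#' @param sample optional sample annotation (list with `sample_id`, `stage`,
#'   `replicate`), carried through to aggregation.
#' @return object of class `score_track`: list with `rrna`, `score`
#'   (length-L numeric with NA for missing), `bond_ends`, `baseline`,
#'   `params`, `sample`.
#' @export
compute_score_track <- function(profile, params = scoring_params(),
                                sample = NULL) {
  L <- length(profile$five_prime_ends)
  nb <- L - 1L
  n <- bond_end_count(profile, seq_len(nb), ends = params$ends)
  w <- .weight_vector(params)
  l <- params$window

  # weighted sums of shifted count vectors; edge flanks excluded by
  # accumulating the available weight mass per position
  wsum_left <- numeric(nb); wmass_left <- numeric(nb)
  wsum_right <- numeric(nb); wmass_right <- numeric(nb)
  avail_left <- integer(nb); avail_right <- integer(nb)
  for (j in seq_len(l)) {
    idx <- seq_len(nb) - j
    ok <- idx >= 1L
    wsum_left[ok] <- wsum_left[ok] + w[j] * n[idx[ok]]
    wmass_left[ok] <- wmass_left[ok] + w[j]
    avail_left[ok] <- avail_left[ok] + 1L
    idx <- seq_len(nb) + j
    ok <- idx <= nb
    wsum_right[ok] <- wsum_right[ok] + w[j] * n[idx[ok]]
    wmass_right[ok] <- wmass_right[ok] + w[j]
    avail_right[ok] <- avail_right[ok] + 1L
  }
  a_left <- ifelse(wmass_left > 0, wsum_left / wmass_left, NA_real_)
  a_right <- ifelse(wmass_right > 0, wsum_right / wmass_right, NA_real_)
  baseline <- (a_left + a_right) / 2
  score <- 1 - n / baseline
  bad <- avail_left < params$min_neighbors |
    avail_right < params$min_neighbors |
    !is.finite(baseline) | baseline < params$min_local_ends
  score[bad] <- NA_real_
  if (params$clamp) score <- pmin(pmax(score, 0), 1)
  structure(
    list(rrna = profile$rrna,
         score = c(score, NA_real_),
         bond_ends = n,
         baseline = c(baseline, NA_real_),
         params = params,
         sample = sample),
    class = "score_track"
  )
}

#' @export
print.score_track <- function(x, ...) {
  ok <- !is.na(x$score)
  cat(sprintf("<score_track> %s: %d scored / %d positions",
              x$rrna, sum(ok), length(x$score)))
  if (!is.null(x$sample)) cat(sprintf(" [sample %s]", x$sample$sample_id))
  cat("\n")
  invisible(x)
}

#' @export
summary.score_track <- function(object, ...) {
  s <- object$score
  cat(sprintf("score track for %s (%d positions)\n", object$rrna, length(s)))
  cat(sprintf("  scored: %d, missing: %d\n", sum(!is.na(s)), sum(is.na(s))))
  print(summary(s[!is.na(s)]))
  invisible(object)
}

#' @export
plot.score_track <- function(x, threshold = NULL, ...) {
  graphics::plot(seq_along(x$score), x$score, type = "h",
                 xlab = sprintf("%s position", x$rrna),
                 ylab = "methylation score", ylim = c(0, 1), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Sample metadata constructor
#'
#' @param sample_id identifier.
#' @param stage developmental stage, one of 2, 10, 16, 23, 32, 45.
#' @param replicate replicate index (1..4 in the profiled design).
#' @return list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, stage, replicate) {
  structure(list(sample_id = sample_id, stage = as.integer(stage),
                 replicate = as.integer(replicate)),
            class = "sample_meta")
}

# per-stage means over non-missing replicate columns
.stage_mean_matrix <- function(scores, samples) {
  stages <- sort(unique(samples$stage))
  out <- matrix(NA_real_, nrow(scores), length(stages),
                dimnames = list(rownames(scores), as.character(stages)))
  for (k in seq_along(stages)) {
    cols <- samples$sample_id[samples$stage == stages[k]]
    m <- rowMeans(scores[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[, k] <- m
  }
  out
}

#' Aggregate replicate score tracks into a sites-by-samples matrix
#'
#' Restricts each sample's tracks to the catalog positions and assembles the
#' score matrix plus per-stage means (arithmetic mean over that stage's
#' non-missing replicates; a stage with no value stays missing).
#'
#' @param tracks named list (by sample_id) of lists of [compute_score_track]
#'   outputs (one per rRNA).
#' @param catalog a `site_catalog` (or any data frame with `rrna`,
#'   `position`, `label`); `NULL` scans every scored position of every rRNA
#'   present (de novo mode).
#' @param samples data frame with `sample_id`, `stage`, `replicate`.
#' @return object of class `score_matrix`: list with `scores` (sites x
#'   samples matrix), `sites`, `samples`, `stage_means` (sites x stages).
#' @export
aggregate_replicates <- function(tracks, catalog, samples) {
  stopifnot(nrow(samples) >= 1L, all(samples$sample_id %in% names(tracks)))
  if (anyDuplicated(paste(samples$stage, samples$replicate))) {
    stop("(stage, replicate) pairs must be unique", call. = FALSE)
  }
  if (is.null(catalog)) {
    first <- tracks[[samples$sample_id[1]]]
    catalog <- do.call(rbind, lapply(first, function(tr) {
      data.frame(rrna = tr$rrna, position = seq_along(tr$score),
                 label = paste0("p", seq_along(tr$score)))
    }))
  }
  n_sites <- nrow(catalog)
  ids <- samples$sample_id
  scores <- matrix(NA_real_, n_sites, length(ids),
                   dimnames = list(paste(catalog$rrna, catalog$label, sep = ":"),
                                   ids))
  for (s in ids) {
    for (tr in tracks[[s]]) {
      sel <- which(catalog$rrna == tr$rrna)
      pos <- catalog$position[sel]
      ok <- pos <= length(tr$score)
      scores[sel[ok], s] <- tr$score[pos[ok]]
    }
  }
  stage_means <- .stage_mean_matrix(scores, samples)
  all_missing <- rowSums(!is.na(scores)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " catalog site(s) have no score in any sample",
            call. = FALSE)
  }
  structure(list(scores = scores, sites = as.data.frame(catalog),
                 samples = as.data.frame(samples), stage_means = stage_means),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d sites x %d samples (%d stages)\n",
              nrow(x$scores), ncol(x$scores), ncol(x$stage_means)))
  invisible(x)
}

#' @export
summary.score_matrix <- function(object, ...) {
  print(object)
  cat("per-stage mean of site means:\n")
  print(round(colMeans(object$stage_means, na.rm = TRUE), 3))
  invisible(object)
}

#' Write a score matrix as CSV
#'
#' One row per site (`rrna`, `position`, `label`), one column per sample;
#' missing scores are written as empty cells and restored as missing on
#' re-read. Round-trips with [read_score_matrix()].
#'
#' @param matrix a `score_matrix`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(matrix, path) {
  df <- data.frame(rrna = matrix$sites$rrna,
                   position = matrix$sites$position,
                   label = matrix$sites$label,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(matrix$scores, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path CSV file.
#' @param samples optional sample metadata data frame (`sample_id`, `stage`,
#'   `replicate`). If omitted, sample ids of the form `s<stage>_r<rep>` are
#'   parsed back into metadata.
#' @return a `score_matrix`.
#' @export
read_score_matrix <- function(path, samples = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("rrna", "position", "label")
  ids <- setdiff(names(df), meta_cols)
  scores <- as.matrix(df[, ids, drop = FALSE])
  mode(scores) <- "numeric"
  rownames(scores) <- paste(df$rrna, df$label, sep = ":")
  if (is.null(samples)) {
    m <- regmatches(ids, regexec("^s([0-9]+)_r([0-9]+)$", ids))
    if (all(lengths(m) == 3L)) {
      samples <- data.frame(
        sample_id = ids,
        stage = as.integer(vapply(m, `[`, "", 2L)),
        replicate = as.integer(vapply(m, `[`, "", 3L)))
    } else {
      samples <- data.frame(sample_id = ids, stage = NA_integer_,
                            replicate = seq_along(ids))
    }
  }
  stage_means <- .stage_mean_matrix(scores, samples)
  structure(list(scores = scores,
                 sites = df[, meta_cols],
                 samples = samples,
                 stage_means = stage_means),
            class = "score_matrix")
}
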