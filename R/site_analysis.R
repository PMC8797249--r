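#' Classify a site as hypomethylated
#'
#' A site is hypomethylated when its methylation score falls strictly below
#' the cutoff (default 0.75): substoichiometric modification across the
#' ribosome population.
#'
#' @param mean_score numeric vector of scores in \[0, 1\] (NA allowed).
#' @param cutoff score cutoff (default 0.75).
#' @return logical vector; `NA` propagates.
#' @export
#' @examples
#' classify_hypomethylated(c(0.74, 0.75, 1.0))
classify_hypomethylated <- function(mean_score, cutoff = 0.75) {
  mean_score < cutoff
}

#' Developmental methylation pattern of a site
#'
#' Labels a site from its per-stage mean scores at a cutoff: `"robust"`
#' when no stage falls below, `"constitutive_hypo"` when all stages do, and
#' `"stage_specific_hypo(S)"` when exactly the stages in `S` do (the
#' headline developmental pattern being `S = {45}`). A site with any
#' missing stage mean is labelled `"other"`.
#'
#' @param per_stage_mean named numeric vector (names = stage numbers).
#' @param cutoff hypomethylation cutoff (default 0.75).
#' @return a single pattern string.
#' @export
#' @examples
#' stage_pattern(c(`2` = .9, `10` = .88, `16` = .9, `23` = .86,
#'                 `32` = .85, `45` = .60))
stage_pattern <- function(per_stage_mean, cutoff = 0.75) {
  if (anyNA(per_stage_mean)) return("other")
  hypo <- per_stage_mean < cutoff
  if (!any(hypo)) return("robust")
  if (all(hypo)) return("constitutive_hypo")
  paste0("stage_specific_hypo(",
         paste(names(per_stage_mean)[hypo], collapse = ","), ")")
}

#' Call methylated sites from a score matrix
#'
#' A position is *detected* when its score reaches `detection_threshold` in
#' at least `min_replicate_fraction` of the non-missing samples of at least
#' one stage. Each called site also carries its overall mean score, its
#' per-stage means, the hypomethylation flag ([classify_hypomethylated()]
#' on the overall mean) and its [stage_pattern()].
#'
#' Run on a catalog-restricted matrix for catalog mode, or on a matrix
#' built with `catalog = NULL` ([aggregate_replicates()]) to scan every
#' position de novo.
#'
#' @param matrix a `score_matrix`.
#' @param detection_threshold minimum score counting as signal (default
#'   0.30).
#' @param min_replicate_fraction fraction of a stage's non-missing
#'   replicates that must reach the threshold (default 0.75).
#' @param cutoff hypomethylation cutoff (default 0.75).
#' @return data frame of class `methylation_calls`: one row per site with
#'   `rrna`, `position`, `label`, `mean_score`, `stage_<s>` columns,
#'   `detected`, `hypomethylated`, `pattern`.
#' @export
call_sites <- function(matrix, detection_threshold = 0.30,
                       min_replicate_fraction = 0.75, cutoff = 0.75) {
  if (!inherits(matrix, "score_matrix") || ncol(matrix$scores) == 0L ||
      nrow(matrix$scores) == 0L) {
    stop("empty or invalid score matrix", call. = FALSE)
  }
  sc <- matrix$scores
  samples <- matrix$samples
  stages <- sort(unique(samples$stage))
  detected <- rep(FALSE, nrow(sc))
  for (st in stages) {
    cols <- samples$sample_id[samples$stage == st]
    sub <- sc[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    n_hit <- rowSums(sub >= detection_threshold, na.rm = TRUE)
    detected <- detected |
      (n_ok > 0L & n_hit >= min_replicate_fraction * n_ok)
  }
  mean_score <- rowMeans(sc, na.rm = TRUE)
  mean_score[is.nan(mean_score)] <- NA_real_
  sm <- matrix$stage_means
  out <- data.frame(rrna = matrix$sites$rrna,
                    position = matrix$sites$position,
                    label = matrix$sites$label,
                    mean_score = mean_score)
  for (st in colnames(sm)) out[[paste0("stage_", st)]] <- sm[, st]
  out$detected <- detected
  out$hypomethylated <- classify_hypomethylated(mean_score, cutoff)
  out$pattern <- apply(sm, 1L, stage_pattern, cutoff = cutoff)
  rownames(out) <- NULL
  class(out) <- c("methylation_calls", "data.frame")
  out
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat(sprintf("<methylation_calls> %d site(s): %d detected, %d hypomethylated\n",
              nrow(x), sum(x$detected, na.rm = TRUE),
              sum(x$hypomethylated, na.rm = TRUE)))
  tab <- table(x$pattern)
  cat("patterns:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare detected sites against a previous map
#'
#' Partitions sites into `confirmed` (previously mapped and detected),
#' `novel` (detected, absent from the previous map) and `undetected`
#' (previously mapped, not detected). The three sets are disjoint and
#' `confirmed` and `undetected` partition the previous map.
#'
#' @param detected character vector of detected site keys, or a
#'   `methylation_calls` data frame (its `detected` rows are used; keys are
#'   `"rrna:position"`).
#' @param previous_map character vector of previously mapped site keys (or
#'   a data frame with `rrna` and `position`).
#' @return list of class `catalog_comparison` with `confirmed`, `novel`,
#'   `undetected`.
#' @export
compare_catalog <- function(detected, previous_map) {
  as_keys <- function(x) {
    if (is.data.frame(x)) {
      if ("detected" %in% names(x)) x <- x[x$detected, , drop = FALSE]
      paste(x$rrna, x$position, sep = ":")
    } else as.character(x)
  }
  det <- unique(as_keys(detected))
  prev <- unique(as_keys(previous_map))
  structure(list(confirmed = sort(intersect(prev, det)),
                 novel = sort(setdiff(det, prev)),
                 undetected = sort(setdiff(prev, det))),
            class = "catalog_comparison")
}

#' @export
print.catalog_comparison <- function(x, ...) {
  cat(sprintf("<catalog_comparison> confirmed %d, novel %d, undetected %d\n",
              length(x$confirmed), length(x$novel), length(x$undetected)))
  invisible(x)
}

#' Cluster samples by their methylation profiles
#'
#' Agglomerative clustering with average linkage on the distance
#' `1 - Pearson correlation` between sample score vectors. Sites with a
#' missing score in any sample are dropped from the distance computation
#' (reported in a message). Returns the dendrogram, its Newick
#' serialization (sample ids as leaves) and the flat cut into `k` groups
#' (default: the number of stages).
#'
#' @param matrix a `score_matrix` with >= 2 samples.
#' @param k number of flat clusters (default: number of distinct stages).
#' @return list of class `sample_clustering` with `hclust`, `newick`,
#'   `groups` (named integer vector), `n_sites_used`.
#' @export
cluster_samples <- function(matrix, k = NULL) {
  sc <- matrix$scores
  if (ncol(sc) < 2L) stop("need at least two samples to cluster",
                          call. = FALSE)
  complete <- rowSums(is.na(sc)) == 0L
  if (sum(complete) < 2L) {
    stop("fewer than two sites with complete scores across samples",
         call. = FALSE)
  }
  if (any(!complete)) {
    message(sum(!complete), " site(s) with missing values dropped from clustering")
  }
  m <- sc[complete, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "average")
  if (is.null(k)) k <- length(unique(matrix$samples$stage))
  groups <- stats::cutree(hc, k = min(k, ncol(m)))
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = newick, groups = groups,
                 n_sites_used = sum(complete)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("<sample_clustering> %d samples, %d sites used, %d groups\n",
              length(x$groups), x$n_sites_used, length(unique(x$groups))))
  invisible(x)
}

#' @export
plot.sample_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "methylation-profile clustering",
       ...)
  invisible(x)
}

#' Do flat clusters coincide with stages?
#'
#' Convenience check of the replicate-clustering property: TRUE when the
#' flat grouping puts two samples together exactly when they share a stage.
#'
#' @param clustering a [cluster_samples()] result.
#' @param samples sample metadata (`sample_id`, `stage`).
#' @return logical scalar.
#' @export
groups_match_stages <- function(clustering, samples) {
  g <- clustering$groups[samples$sample_id]
  st <- samples$stage
  all(outer(g, g, "==") == outer(st, st, "=="))
}

#' Summarize catalog composition
#'
#' Counts of total, per-rRNA, novel and orthogonally validated sites in a
#' site catalog.
#'
#' @param catalog a `site_catalog`.
#' @return list of counts.
#' @export
catalog_summary <- function(catalog) {
  per_rrna <- table(catalog$rrna)
  novel <- !catalog$previously_mapped
  list(n_sites = nrow(catalog),
       per_rrna = as.list(per_rrna),
       n_novel = sum(novel),
       novel_per_rrna = as.list(table(catalog$rrna[novel])),
       n_validated = sum(catalog$low_dntp_validated),
       n_validated_novel = sum(catalog$low_dntp_validated & novel))
}

#' Summarize hypomethylation at a cutoff
#'
#' The notion of "percent hypomethylated" admits several readings; all are
#' reported: by the overall site mean, by *all* stage means below the
#' cutoff (constitutive), and by *any* stage mean below it. Pattern counts
#' (constitutive, stage-45-only) are included per rRNA.
#'
#' @param calls a `methylation_calls` data frame (or any data frame with
#'   `rrna`, `mean_score` and `stage_<s>` columns).
#' @param cutoff hypomethylation cutoff (default 0.75).
#' @return list of percentages and counts.
#' @export
hypomethylation_summary <- function(calls, cutoff = 0.75) {
  stage_cols <- grep("^stage_", names(calls), value = TRUE)
  sm <- as.matrix(calls[, stage_cols, drop = FALSE])
  all_below <- rowSums(sm < cutoff) == ncol(sm)
  any_below <- rowSums(sm < cutoff) > 0L
  only45 <- rep(FALSE, nrow(calls))
  if ("stage_45" %in% stage_cols) {
    others <- setdiff(stage_cols, "stage_45")
    only45 <- calls$stage_45 < cutoff &
      rowSums(as.matrix(calls[, others, drop = FALSE]) < cutoff) == 0L
  }
  n <- nrow(calls)
  list(n_sites = n,
       pct_overall_mean = 100 * sum(calls$mean_score < cutoff, na.rm = TRUE) / n,
       pct_all_stages = 100 * sum(all_below, na.rm = TRUE) / n,
       pct_any_stage = 100 * sum(any_below, na.rm = TRUE) / n,
       n_constitutive = sum(all_below, na.rm = TRUE),
       n_stage45_only = sum(only45, na.rm = TRUE),
       constitutive_per_rrna = as.list(table(calls$rrna[which(all_below)])),
       stage45_only_per_rrna = as.list(table(calls$rrna[which(only45)])))
}

#' Write methylation calls as CSV
#'
#' @param calls a `methylation_calls` data frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(as.data.frame(calls), path, row.names = FALSE, na = "")
  invisible(path)
}
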