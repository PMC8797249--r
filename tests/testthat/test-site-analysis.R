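make_matrix <- function(values, stages, replicates = 2L) {
  # values: named list site_label -> per-stage mean vector; replicates get
  # identical scores so stage means equal the given values
  ids <- as.vector(t(outer(stages, seq_len(replicates),
                           function(s, r) sprintf("s%d_r%d", s, r))))
  samples <- data.frame(sample_id = ids,
                        stage = rep(stages, each = replicates),
                        replicate = rep(seq_len(replicates), length(stages)))
  scores <- do.call(rbind, lapply(values, function(v) {
    rep(v, each = replicates)
  }))
  rownames(scores) <- paste0("x:", names(values))
  colnames(scores) <- ids
  sites <- data.frame(rrna = "x", position = seq_along(values) * 10L,
                      label = names(values))
  sm <- do.call(rbind, values)
  dimnames(sm) <- list(rownames(scores), as.character(stages))
  structure(list(scores = scores, sites = sites, samples = samples,
                 stage_means = sm), class = "score_matrix")
}

STAGES <- c(2L, 10L, 16L, 23L, 32L, 45L)

test_that("hypomethylation classification uses a strict cutoff", {
  expect_true(classify_hypomethylated(0.74))
  expect_false(classify_hypomethylated(0.75))
  expect_false(classify_hypomethylated(1.0))
  expect_true(is.na(classify_hypomethylated(NA_real_)))
})

test_that("stage patterns partition sites into the documented classes", {
  v45 <- c(`2` = 0.9, `10` = 0.88, `16` = 0.9, `23` = 0.86, `32` = 0.85,
           `45` = 0.60)
  expect_equal(stage_pattern(v45), "stage_specific_hypo(45)")
  expect_equal(stage_pattern(setNames(rep(0.5, 6), STAGES)),
               "constitutive_hypo")
  expect_equal(stage_pattern(setNames(rep(0.9, 6), STAGES)), "robust")
  v45na <- v45; v45na[2] <- NA
  expect_equal(stage_pattern(v45na), "other")

  # every site gets exactly one label (partition property)
  set.seed(12)
  for (k in 1:50) {
    v <- setNames(runif(6), STAGES)
    p <- stage_pattern(v)
    expect_length(p, 1L)
    expect_match(p, "^(robust|constitutive_hypo|stage_specific_hypo\\(.+\\)|other)$")
  }
})

test_that("site calling applies detection and replicate-fraction rules", {
  m <- make_matrix(list(high = rep(0.9, 6), low = rep(0.05, 6),
                        late = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.6)), STAGES)
  calls <- call_sites(m)
  expect_true(calls$detected[calls$label == "high"])
  expect_false(calls$detected[calls$label == "low"])
  expect_equal(calls$pattern[calls$label == "late"],
               "stage_specific_hypo(45)")
  expect_error(call_sites(structure(list(scores = matrix(numeric(0), 0, 0)),
                                    class = "score_matrix")), "empty")
})

test_that("lowering the cutoff never increases the hypomethylated count", {
  set.seed(77)
  values <- lapply(1:30, function(i) setNames(runif(6), STAGES))
  names(values) <- paste0("s", 1:30)
  m <- make_matrix(values, STAGES)
  cuts <- c(0.2, 0.5, 0.75, 0.9)
  counts <- vapply(cuts, function(ct) {
    sum(call_sites(m, cutoff = ct)$hypomethylated, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("catalog comparison partitions correctly", {
  cmp <- compare_catalog(c("x:2", "x:3"), c("x:1", "x:2"))
  expect_equal(cmp$confirmed, "x:2")
  expect_equal(cmp$novel, "x:3")
  expect_equal(cmp$undetected, "x:1")

  cmp2 <- compare_catalog(c("x:1", "x:2"), c("x:1", "x:2"))
  expect_length(cmp2$novel, 0L)

  # set identities on random inputs
  set.seed(5)
  for (k in 1:25) {
    det <- sample(paste0("p", 1:40), sample(0:20, 1))
    prev <- sample(paste0("p", 1:40), sample(0:20, 1))
    cmp <- compare_catalog(det, prev)
    expect_length(intersect(cmp$confirmed, cmp$novel), 0L)
    expect_length(intersect(cmp$confirmed, cmp$undetected), 0L)
    expect_length(intersect(cmp$novel, cmp$undetected), 0L)
    expect_setequal(c(cmp$confirmed, cmp$undetected), unique(prev))
    expect_setequal(c(cmp$confirmed, cmp$novel), unique(det))
  }
})

test_that("novel sites planted in a synthetic series are recovered as novel", {
  ref <- demo_rrna_reference(length = 900L)
  positions <- seq(80L, 820L, by = 60L)  # 13 sites
  f <- rep(0.9, length(positions))
  stages <- STAGES
  specs <- lapply(stages, function(s) {
    methylation_spec(ref$name, positions, f)
  })
  names(specs) <- stages
  series <- simulate_embryo_series(
    list(rRNA_demo = ref), stage_design(specs, replicates = 2L),
    fragmentation_config(molecules = 8000L, seed = 400L))
  params <- scoring_params()
  tracks <- lapply(series$samples, function(s) {
    lapply(s$profiles, compute_score_track, params = params)
  })
  catalog <- data.frame(rrna = ref$name, position = positions,
                        label = paste0("p", positions))
  m <- aggregate_replicates(tracks, catalog, series$samples_df)
  calls <- call_sites(m)
  expect_true(all(calls$detected))
  known <- paste0(ref$name, ":", positions[1:10])
  cmp <- compare_catalog(calls, known)
  expect_setequal(cmp$novel, paste0(ref$name, ":", positions[11:13]))
  expect_length(cmp$undetected, 0L)
})

test_that("clustering groups replicates, is order- and scale-invariant", {
  set.seed(31)
  base <- lapply(1:12, function(i) {
    f0 <- runif(1, 0.3, 0.9)
    step <- (seq_len(6) - 1) * 0.05 * sample(c(-1, 1), 1)
    pmin(pmax(f0 + step, 0), 1)
  })
  names(base) <- paste0("site", 1:12)
  # two replicates with small independent noise
  ids <- as.vector(t(outer(STAGES, 1:2, function(s, r)
    sprintf("s%d_r%d", s, r))))
  samples <- data.frame(sample_id = ids, stage = rep(STAGES, each = 2),
                        replicate = rep(1:2, 6))
  scores <- do.call(rbind, lapply(base, function(v) {
    rep(v, each = 2) + rnorm(12, 0, 0.01)
  }))
  rownames(scores) <- paste0("x:", names(base))
  colnames(scores) <- ids
  m <- structure(list(scores = scores,
                      sites = data.frame(rrna = "x",
                                         position = seq_len(12) * 10L,
                                         label = names(base)),
                      samples = samples,
                      stage_means = NULL), class = "score_matrix")
  cl <- cluster_samples(m)
  expect_true(groups_match_stages(cl, samples))
  expect_match(cl$newick, "s2_r1")

  # sample order invariance of the induced partition
  perm <- sample(ncol(scores))
  m2 <- m; m2$scores <- scores[, perm]; m2$samples <- samples[perm, ]
  cl2 <- cluster_samples(m2)
  expect_true(groups_match_stages(cl2, samples))

  # affine rescaling leaves correlation distances unchanged
  m3 <- m; m3$scores <- 0.5 * scores + 0.2
  cl3 <- cluster_samples(m3)
  g1 <- cl$groups[colnames(scores)]
  g3 <- cl3$groups[colnames(scores)]
  expect_true(all(outer(g1, g1, "==") == outer(g3, g3, "==")))

  # identical samples merge first (distance 0)
  m4 <- m
  m4$scores[, 2] <- m4$scores[, 1]
  cl4 <- cluster_samples(m4)
  expect_equal(cl4$hclust$height[1], 0, tolerance = 1e-12)

  # degenerate inputs error
  m5 <- m; m5$scores <- scores[, 1, drop = FALSE]
  expect_error(cluster_samples(m5), "two samples")
  m6 <- m; m6$scores[1:11, 1] <- NA
  expect_error(suppressMessages(cluster_samples(m6)), "complete")
})

test_that("hypomethylation summaries agree across their three readings", {
  vals <- list(robust = rep(0.9, 6),
               con = rep(0.5, 6),
               late = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.5))
  m <- make_matrix(vals, STAGES)
  calls <- call_sites(m)
  s <- hypomethylation_summary(calls)
  expect_equal(s$n_sites, 3L)
  expect_equal(s$n_constitutive, 1L)
  expect_equal(s$n_stage45_only, 1L)
  expect_equal(s$pct_all_stages, 100 / 3)
  expect_equal(s$pct_any_stage, 200 / 3)
  # overall mean of the late site: (5 * 0.9 + 0.5) / 6 > 0.75 -> not hypo
  expect_equal(s$pct_overall_mean, 100 / 3)
})
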