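#' Demonstration reference and stage design
#'
#' A compact, fully synthetic study used by the command layer, the test
#' suite and the examples: one 1800-nt rRNA-like reference carrying 20
#' methylated sites that cover every developmental pattern class —
#' robustly methylated sites, constitutively hypomethylated sites,
#' stage-45-only hypomethylated sites, and monotone developmental "ramp"
#' sites whose stoichiometry moves by 0.2 between consecutive stages (the
#' feature that lets profile clustering separate all six stages).
#'
#' @param length reference length (default 1800).
#' @param seed seed fixing the demo sequence (default 42; change to get a
#'   different but equally valid demo reference).
#' @return an [rrna_reference] named `"rRNA_demo"`.
#' @export
demo_rrna_reference <- function(length = 1800L, seed = 42L) {
  seqs <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = "")
  })
  rrna_reference("rRNA_demo", seqs)
}

#' @rdname demo_rrna_reference
#' @param ref the demo reference.
#' @param replicates,replicate_noise passed to [stage_design()].
#' @return for `demo_stage_design()`: a [stage_design] whose per-stage
#'   specs follow the built-in site plan (see `demo_site_plan()`).
#' @export
demo_stage_design <- function(ref = demo_rrna_reference(), replicates = 4L,
                              replicate_noise = 0.02) {
  plan <- demo_site_plan(ref)
  stages <- c(2L, 10L, 16L, 23L, 32L, 45L)
  specs <- lapply(seq_along(stages), function(k) {
    methylation_spec(plan$rrna, plan$position, plan[[paste0("f_", stages[k])]])
  })
  names(specs) <- as.character(stages)
  stage_design(specs, replicates = replicates,
               replicate_noise = replicate_noise, stages = stages)
}

#' @rdname demo_rrna_reference
#' @return for `demo_site_plan()`: a data frame with the site positions,
#'   classes and per-stage ground-truth stoichiometries `f_<stage>`.
#' @export
demo_site_plan <- function(ref = demo_rrna_reference()) {
  # ~1 site per 45 nt, matching the density of the profiled rRNA repertoire
  position <- seq(100L, by = 42L, length.out = 40L)
  class <- c(rep("robust", 18L), rep("constitutive_hypo", 6L),
             rep("stage45_hypo", 6L), rep("ramp_down", 5L), rep("ramp_up", 5L))
  f_by_stage <- list(
    robust = rep(0.95, 6),
    constitutive_hypo = rep(0.45, 6),
    stage45_hypo = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.45),
    ramp_down = c(1, 0.8, 0.6, 0.4, 0.2, 0),
    ramp_up = c(0, 0.2, 0.4, 0.6, 0.8, 1))
  stages <- c(2L, 10L, 16L, 23L, 32L, 45L)
  out <- data.frame(rrna = ref$name, position = position, class = class)
  out$nucleotide <- substring(ref$sequence, position, position)
  out$label <- site_label(out$nucleotide, position)
  for (k in seq_along(stages)) {
    out[[paste0("f_", stages[k])]] <-
      vapply(class, function(cl) f_by_stage[[cl]][k], numeric(1))
  }
  out
}
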