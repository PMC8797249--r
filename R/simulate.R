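#' Methylation specification (ground-truth stoichiometries)
#'
#' A methylation spec assigns each (rRNA, position) a stoichiometry
#' `f` in \[0, 1\]: the fraction of molecules 2'-O-methylated at that
#' residue. In the generative model, methylation at residue `b` protects
#' the phosphodiester bond 3' of `b` (bond `b`) from alkaline cleavage.
#'
#' @param rrna character vector of reference names.
#' @param position integer vector of 1-based residue positions.
#' @param f numeric vector of stoichiometries in \[0, 1\].
#' @return data frame of class `methylation_spec`.
#' @export
methylation_spec <- function(rrna, position, f) {
  df <- data.frame(rrna = rrna, position = as.integer(position), f = f)
  if (any(df$f < 0 | df$f > 1)) stop("stoichiometries must lie in [0, 1]",
                                     call. = FALSE)
  if (any(df$position < 1L)) stop("positions are 1-based", call. = FALSE)
  class(df) <- c("methylation_spec", "data.frame")
  df
}

# dense per-residue stoichiometry vector for one reference
.f_vector <- function(spec, ref) {
  f <- numeric(ref$length)
  if (is.null(spec)) return(f)
  sub <- spec[spec$rrna == ref$name, , drop = FALSE]
  if (nrow(sub) && any(sub$position > ref$length)) {
    stop("methylation spec position beyond end of ", ref$name, call. = FALSE)
  }
  f[sub$position] <- sub$f
  f
}

#' Fragmentation simulation settings
#'
#' Models mild alkaline hydrolysis: every internal bond of every template
#' molecule is cleaved independently, and fragments within the retained
#' length window enter the library. With `cleavage_prob = 0.03` the mean
#' fragment length is ~33 nt, matching a protocol tuned for short (~20-30
#' nt) fragments; the retained window is slightly wider by default so local
#' baseline estimation is exercised under mild coverage waviness.
#'
#' @param molecules number of template molecules (default 20000).
#' @param cleavage_prob per-bond cleavage probability `p0` in (0, 1)
#'   (default 0.03).
#' @param min_len,max_len retained fragment length bounds (defaults 20, 50).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return list of class `fragmentation_config`.
#' @export
fragmentation_config <- function(molecules = 20000L, cleavage_prob = 0.03,
                                 min_len = 20L, max_len = 50L, seed = NULL) {
  if (cleavage_prob <= 0 || cleavage_prob >= 1) {
    stop("cleavage_prob must lie in (0, 1)", call. = FALSE)
  }
  if (min_len > max_len) stop("min_len must not exceed max_len", call. = FALSE)
  structure(list(molecules = as.integer(molecules),
                 cleavage_prob = cleavage_prob,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed = seed),
            class = "fragmentation_config")
}

#' Simulate alkaline fragmentation of one rRNA
#'
#' Per-molecule generative model: each internal bond `b` (1..L-1) of each of
#' `cfg$molecules` molecules is cleaved independently with probability
#' `p0 * (1 - f(b))`, where `f(b)` is the methylation stoichiometry of
#' residue `b` — a fully methylated residue fully protects its 3'-adjacent
#' bond. Cleavage points partition each molecule into fragments; fragments
#' with length in `[min_len, max_len]` are retained and their 5'/3' ends
#' counted. Because fragments are generated per molecule, the number of
#' retained fragments equals both end-count totals exactly.
#'
#' @param ref an [rrna_reference].
#' @param spec a [methylation_spec] (or `NULL` for no methylation).
#' @param cfg a [fragmentation_config].
#' @return list with `fragments` (data frame of 1-based closed intervals
#'   `start`, `end`) and `profile` (an [end_count_profile]).
#' @export
simulate_fragmentation <- function(ref, spec = NULL,
                                   cfg = fragmentation_config()) {
  L <- ref$length
  if (1 / cfg$cleavage_prob < cfg$min_len) {
    warning("expected fragment length below min_len; few fragments retained",
            call. = FALSE)
  }
  f <- .f_vector(spec, ref)
  pb <- cfg$cleavage_prob * (1 - f[seq_len(L - 1L)])
  nmol <- cfg$molecules
  with_seed(cfg$seed, {
    ncut <- stats::rbinom(L - 1L, nmol, pb)
    bond <- rep.int(seq_len(L - 1L), ncut)
    mol <- unlist(lapply(seq_len(L - 1L), function(b) {
      if (ncut[b] > 0L) sample.int(nmol, ncut[b]) else integer(0)
    }), use.names = FALSE)
    o <- order(mol, bond)
    mol <- mol[o]; bond <- bond[o]
    if (length(bond)) {
      first <- !duplicated(mol)
      start <- c(1L, bond[-length(bond)] + 1L)
      start[first] <- 1L
      end <- bond
      last <- c(first[-1L], TRUE)
      t_start <- bond[last] + 1L
    } else {
      first <- logical(0)
      start <- end <- t_start <- integer(0)
    }
    # molecules with no cut yield one full-length fragment
    n_uncut <- nmol - sum(first)
    s <- c(start, t_start, rep.int(1L, n_uncut))
    e <- c(end, rep.int(L, length(t_start) + n_uncut))
    len <- e - s + 1L
    keep <- len >= cfg$min_len & len <= cfg$max_len
    s <- s[keep]; e <- e[keep]
    list(fragments = data.frame(start = s, end = e),
         profile = end_count_profile(ref$name, tabulate(s, L), tabulate(e, L)))
  })
}

#' Multi-stage embryo series design
#'
#' The profiled design: six developmental stages (2, 10, 16, 23, 32, 45),
#' four individually sequenced embryos per stage. Each stage has its own
#' ground-truth [methylation_spec]; each replicate embryo perturbs the
#' stage truth by a truncated-Gaussian deviate of standard deviation
#' `replicate_noise` (small by default: replicate profiles of one stage
#' cluster tightly).
#'
#' @param specs named list of [methylation_spec], one per stage; names are
#'   the stage numbers.
#' @param replicates embryos per stage (default 4).
#' @param replicate_noise sd of the per-replicate perturbation of `f`,
#'   truncated into \[0, 1\] (default 0.02).
#' @param stages integer vector of stages (default the six profiled ones).
#' @return list of class `stage_design`.
#' @export
stage_design <- function(specs, replicates = 4L, replicate_noise = 0.02,
                         stages = c(2L, 10L, 16L, 23L, 32L, 45L)) {
  if (!all(as.character(stages) %in% names(specs))) {
    stop("specs must contain one methylation_spec per stage: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  if (replicates < 1L) stop("need at least one replicate", call. = FALSE)
  structure(list(stages = as.integer(stages), specs = specs,
                 replicates = as.integer(replicates),
                 replicate_noise = replicate_noise),
            class = "stage_design")
}

#' Simulate a replicated multi-stage embryo series
#'
#' One fragmentation run per (stage, replicate, rRNA). Per-replicate seeds
#' are derived deterministically from `cfg$seed` and the (stage, replicate)
#' labels via [derive_seed()], so any subset of the series is reproducible
#' in isolation. The replicate-specific effective stoichiometries (stage
#' truth plus truncated-Gaussian noise) are returned as the truth table.
#'
#' @param refs named list of [rrna_reference].
#' @param design a [stage_design].
#' @param cfg a [fragmentation_config]; `cfg$seed` is the root seed.
#' @return list with `samples` (per sample_id: list of `profiles`, `meta`),
#'   `samples_df` (sample metadata), and `truth` (per-sample effective `f`).
#' @export
simulate_embryo_series <- function(refs, design, cfg = fragmentation_config()) {
  samples <- list()
  truth <- list()
  meta <- list()
  for (st in design$stages) {
    spec <- design$specs[[as.character(st)]]
    for (r in seq_len(design$replicates)) {
      id <- sprintf("s%d_r%d", st, r)
      sd_rep <- derive_seed(if (is.null(cfg$seed)) 0L else cfg$seed,
                            "stage", st, "rep", r)
      f_rep <- with_seed(sd_rep, {
        pmin(pmax(spec$f + stats::rnorm(nrow(spec), 0, design$replicate_noise),
                  0), 1)
      })
      spec_rep <- methylation_spec(spec$rrna, spec$position, f_rep)
      profiles <- list()
      for (nm in names(refs)) {
        cfg_r <- cfg
        cfg_r$seed <- derive_seed(sd_rep, "rrna", nm)
        profiles[[nm]] <- simulate_fragmentation(refs[[nm]], spec_rep,
                                                 cfg_r)$profile
      }
      samples[[id]] <- list(profiles = profiles,
                            meta = sample_meta(id, st, r))
      truth[[id]] <- data.frame(sample_id = id, stage = st, replicate = r,
                                rrna = spec_rep$rrna,
                                position = spec_rep$position,
                                f_true = spec_rep$f)
      meta[[id]] <- data.frame(sample_id = id, stage = st, replicate = r)
    }
  }
  list(samples = samples,
       samples_df = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a reverse-transcriptase stop profile
#'
#' Reverse transcriptase initiates at `primer_start` and walks 3'->5' along
#' the template. Opposite residue `i` it terminates with probability
#' `f(i) * s(condition) + background`, where `s("low") = 0.8` under limiting
#' dNTPs and `s("regular") = 0.05` under normal dNTPs; the cDNA 3' end of a
#' stop opposite residue `i` is recorded one nucleotide 3' of it, at
#' `i + stop_offset` (default +1). Read-throughs that reach position 1 are
#' counted in `total_reads` but leave no stop.
#'
#' @param ref an [rrna_reference].
#' @param spec a [methylation_spec] (or `NULL`).
#' @param condition `"low"` or `"regular"` dNTP concentration.
#' @param depth number of primer-extension reads (> 0).
#' @param seed RNG seed.
#' @param primer_start 1-based position where extension starts (default: the
#'   3' end of the reference); stops are only observable 5' of it.
#' @param stop_offset recorded stop position relative to the pausing
#'   residue (0 or 1; default 1).
#' @param s_low,s_regular condition-specific termination efficiencies at a
#'   fully methylated residue.
#' @param background per-nucleotide background stop probability.
#' @return object of class `stop_profile`: list with `rrna`, `condition`,
#'   `stops` (length-L counts of cDNA 3' ends), `total_reads`,
#'   `primer_start`.
#' @export
simulate_primer_extension <- function(ref, spec, condition = c("low", "regular"),
                                      depth, seed = NULL,
                                      primer_start = ref$length,
                                      stop_offset = 1L,
                                      s_low = 0.8, s_regular = 0.05,
                                      background = 0.002) {
  condition <- match.arg(condition)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (primer_start < 2L || primer_start > ref$length) {
    stop("primer_start out of range", call. = FALSE)
  }
  s <- if (condition == "low") s_low else s_regular
  f <- .f_vector(spec, ref)
  walk <- seq(primer_start - 1L, 1L)           # residues in walking order
  q <- pmin(background + f[walk] * s, 1)
  surv <- c(1, cumprod(1 - q))                 # P(reach residue walk[k])
  p_stop <- surv[seq_along(walk)] * q          # P(stop at walk[k])
  cum <- cumsum(p_stop)
  stops_at <- with_seed(seed, {
    u <- stats::runif(depth)
    idx <- findInterval(u, cum) + 1L           # index into walk, > n = read-through
    idx[idx <= length(walk)]
  })
  stops <- tabulate(walk[stops_at] + stop_offset, ref$length)
  structure(list(rrna = ref$name, condition = condition, stops = stops,
                 total_reads = as.integer(depth),
                 primer_start = as.integer(primer_start),
                 stop_offset = as.integer(stop_offset)),
            class = "stop_profile")
}

#' @export
print.stop_profile <- function(x, ...) {
  cat(sprintf("<stop_profile> %s [%s dNTP]: %d reads, %d stops\n",
              x$rrna, x$condition, x$total_reads, sum(x$stops)))
  invisible(x)
}

#' Write stop profiles as TSV
#'
#' Columns `rrna`, `position`, `stops`, `condition`, `total_reads`; one row
#' per position per profile.
#' @param profiles list of `stop_profile` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stop_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(rrna = p$rrna, position = seq_along(p$stops),
               stops = p$stops, condition = p$condition,
               total_reads = p$total_reads)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read stop profiles written by [write_stop_profiles()]
#'
#' @param path TSV file.
#' @return list of `stop_profile` objects, one per (rrna, condition).
#' @export
read_stop_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$rrna, df$condition))) {
    sub <- df[paste(df$rrna, df$condition) == key, ]
    L <- max(sub$position)
    stops <- integer(L)
    stops[sub$position] <- sub$stops
    p <- structure(list(rrna = sub$rrna[1], condition = sub$condition[1],
                        stops = stops, total_reads = sub$total_reads[1],
                        primer_start = L, stop_offset = 1L),
                   class = "stop_profile")
    out[[length(out) + 1L]] <- p
  }
  out
}
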