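#' Packaged Xenopus laevis-style catalog fixtures
#'
#' The package ships a distilled site catalog, per-stage score table and
#' snoRNA assignment table for the profiled X. laevis rRNA repertoire:
#' 103 2'-O-methylated positions (34 on 18S, 2 on 5.8S, 67 on 28S), of
#' which 15 are novel and 23 orthogonally validated by low-dNTP primer
#' extension, together with one box C/D snoRNA assignment per site (49 of
#' them novel candidates without a known Rfam family).
#'
#' The underlying reference *sequences* and all values not individually
#' published (filler site positions, per-stage score values, counterpart
#' labels of unnamed sites) are synthetic stand-ins, generated by
#' `data-raw/make_fixtures.R` (filenames carry the `_synthetic` tag);
#' every named residue, flag and count follows the published repertoire.
#'
#' @return `xl_rrna_references()`: named list of [rrna_reference] (18S,
#'   5.8S, 28S; synthetic sequences of realistic lengths).
#' @export
xl_rrna_references <- function() {
  read_rrna_fasta(system.file("extdata", "xl_rrna_synthetic.fasta",
                              package = "ribomethr", mustWork = TRUE))
}

#' @rdname xl_rrna_references
#' @param refs references used to cross-validate the catalog (default: the
#'   packaged ones).
#' @return `xl_site_catalog()`: a `site_catalog` with 103 entries.
#' @export
xl_site_catalog <- function(refs = xl_rrna_references()) {
  read_site_catalog(system.file("extdata", "xl_site_catalog_synthetic.csv",
                                package = "ribomethr", mustWork = TRUE),
                    refs = refs)
}

#' @rdname xl_rrna_references
#' @return `xl_stage_scores()`: data frame with one row per catalog site,
#'   per-stage mean methylation scores (`stage_2` ... `stage_45`) and the
#'   overall `mean_score`.
#' @export
xl_stage_scores <- function() {
  df <- utils::read.csv(system.file("extdata", "xl_stage_scores_synthetic.csv",
                                    package = "ribomethr", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stage_cols <- grep("^stage_", names(df), value = TRUE)
  df$mean_score <- rowMeans(df[, stage_cols])
  df
}

#' @rdname xl_rrna_references
#' @return `xl_snorna_assignments()`: data frame with one snoRNA
#'   assignment per catalog site; an empty `rfam_family` marks a novel
#'   candidate.
#' @export
xl_snorna_assignments <- function() {
  df <- utils::read.csv(system.file("extdata",
                                    "xl_snorna_assignments_synthetic.csv",
                                    package = "ribomethr", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  df$rfam_family[is.na(df$rfam_family)] <- ""
  df
}
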