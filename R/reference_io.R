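#' rRNA reference sequences
#'
#' An `rrna_reference` is a named RNA sequence with 1-based residue
#' coordinates. The internal phosphodiester bond `b` (for `b` in
#' `1..length-1`) joins residues `b` and `b+1`; protection scoring and the
#' fragmentation model are defined on these bonds.
#'
#' @param name identifier, e.g. `"18S"`.
#' @param sequence nucleotide string; T/U and lower case accepted, stored as
#'   upper-case RNA (U).
#' @return object of class `rrna_reference` with fields `name`, `sequence`,
#'   `length`.
#' @export
#' @examples
#' rrna_reference("18S", "ACGUACGU")
rrna_reference <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- .norm_rna(sequence, what = sprintf("record '%s'", name))
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "rrna_reference"
  )
}

#' @export
print.rrna_reference <- function(x, ...) {
  cat(sprintf("<rrna_reference> %s: %d nt\n", x$name, x$length))
  invisible(x)
}

#' Read rRNA reference sequences from FASTA
#'
#' One `rrna_reference` per record; the header token before the first
#' whitespace is the name. T is normalized to U.
#'
#' @param path FASTA file.
#' @return named list of [rrna_reference] objects.
#' @export
read_rrna_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  refs <- lapply(seq_along(set), function(i) {
    rrna_reference(nm[i], as.character(set[[i]]))
  })
  names(refs) <- nm
  refs
}

#' Write rRNA references (or any named RNA sequences) as FASTA
#'
#' @param refs named list of [rrna_reference] objects, or a named character
#'   vector of sequences.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_rrna_fasta <- function(refs, path, width = 70L) {
  if (is.list(refs)) {
    seqs <- vapply(refs, function(r) r$sequence, "")
    names(seqs) <- vapply(refs, function(r) r$name, "")
  } else {
    seqs <- refs
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Site label from nucleotide and position
#'
#' The conventional Nm label: nucleotide letter, "m", then the 1-based
#' position in decimal (e.g. `"Am963"`).
#' @param nucleotide one of A/C/G/U.
#' @param position 1-based integer position.
#' @return character vector of labels.
#' @export
site_label <- function(nucleotide, position) {
  paste0(nucleotide, "m", as.integer(position))
}

#' Read a 2'-O-methylation site catalog
#'
#' Expects a CSV with columns `rrna`, `position`, `nucleotide`,
#' `previously_mapped`, `low_dntp_validated`, `human_counterpart` (empty for
#' sites without a human equivalent). When references are supplied, every
#' entry is cross-checked: the position must be in range and the catalog
#' nucleotide must match the reference sequence.
#'
#' @param path CSV file.
#' @param refs optional named list of [rrna_reference] for validation.
#' @return data frame of class `site_catalog` with an added `label` column.
#' @export
read_site_catalog <- function(path, refs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rrna", "position", "nucleotide", "previously_mapped",
            "low_dntp_validated", "human_counterpart")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$position <- as.integer(df$position)
  df$nucleotide <- toupper(chartr("Tt", "Uu", df$nucleotide))
  df$previously_mapped <- as.logical(df$previously_mapped)
  df$low_dntp_validated <- as.logical(df$low_dntp_validated)
  df$human_counterpart[is.na(df$human_counterpart)] <- ""
  validate_site_catalog(df, refs)
}

#' Validate (and label) a site-catalog data frame
#'
#' @param df data frame with the catalog columns.
#' @param refs optional references for sequence cross-checks.
#' @return the validated `site_catalog`.
#' @export
validate_site_catalog <- function(df, refs = NULL) {
  if (any(df$position < 1L)) {
    stop("positions are 1-based; found position ",
         min(df$position), call. = FALSE)
  }
  if (!all(df$nucleotide %in% names(.RNA_CODES))) {
    bad <- df$nucleotide[!df$nucleotide %in% names(.RNA_CODES)][1]
    stop("invalid catalog nucleotide: ", bad, call. = FALSE)
  }
  key <- paste(df$rrna, df$position)
  if (anyDuplicated(key)) {
    stop("duplicate catalog entry: ", key[duplicated(key)][1], call. = FALSE)
  }
  df$label <- site_label(df$nucleotide, df$position)
  if (!is.null(refs)) {
    for (i in seq_len(nrow(df))) {
      ref <- refs[[df$rrna[i]]]
      if (is.null(ref)) {
        stop("catalog rRNA '", df$rrna[i], "' not among references",
             call. = FALSE)
      }
      if (df$position[i] > ref$length) {
        stop("site ", df$rrna[i], ":", df$label[i],
             " beyond reference length ", ref$length, call. = FALSE)
      }
      have <- substr(ref$sequence, df$position[i], df$position[i])
      if (have != df$nucleotide[i]) {
        stop("site ", df$rrna[i], ":", df$label[i],
             " disagrees with reference (", have, " at position ",
             df$position[i], ")", call. = FALSE)
      }
    }
  }
  class(df) <- c("site_catalog", "data.frame")
  df
}

#' End-count profile
#'
#' Per-position counts of retained-fragment 5' and 3' ends on one rRNA in
#' one sample — the raw quantitative signal of the protocol.
#'
#' @param rrna reference name.
#' @param five_prime_ends,three_prime_ends non-negative integer vectors of
#'   length `length`.
#' @param length reference length (defaults to the vector length).
#' @return object of class `end_count_profile` with fields `rrna`,
#'   `five_prime_ends`, `three_prime_ends`, `n_fragments`.
#' @export
end_count_profile <- function(rrna, five_prime_ends, three_prime_ends,
                              length = base::length(five_prime_ends)) {
  stopifnot(base::length(five_prime_ends) == length,
            base::length(three_prime_ends) == length)
  if (any(five_prime_ends < 0) || any(three_prime_ends < 0)) {
    stop("negative end counts in profile for ", rrna, call. = FALSE)
  }
  structure(
    list(rrna = rrna,
         five_prime_ends = as.integer(five_prime_ends),
         three_prime_ends = as.integer(three_prime_ends),
         n_fragments = sum(as.numeric(five_prime_ends))),
    class = "end_count_profile"
  )
}

#' @export
print.end_count_profile <- function(x, ...) {
  cat(sprintf("<end_count_profile> %s: %d positions, %g fragment 5' ends\n",
              x$rrna, length(x$five_prime_ends), x$n_fragments))
  invisible(x)
}

#' Read end-count tables (TSV)
#'
#' Columns exactly `rrna`, `position`, `five_prime_ends`,
#' `three_prime_ends`, one row per covered position. Missing positions are
#' densified to zero counts.
#'
#' @param path TSV file.
#' @param refs named list of [rrna_reference]; used to size the dense
#'   profiles and range-check positions. If `NULL`, each profile is sized by
#'   its largest observed position.
#' @return named list of [end_count_profile], one per rRNA.
#' @export
read_end_counts <- function(path, refs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rrna", "position", "five_prime_ends", "three_prime_ends")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("end-count table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty end-count table: ", path, call. = FALSE)
  if (any(df$five_prime_ends < 0) || any(df$three_prime_ends < 0)) {
    stop("negative counts in ", path, call. = FALSE)
  }
  out <- list()
  for (nm in unique(df$rrna)) {
    sub <- df[df$rrna == nm, ]
    L <- if (!is.null(refs)) {
      if (is.null(refs[[nm]])) stop("rRNA '", nm, "' not among references",
                                    call. = FALSE)
      refs[[nm]]$length
    } else max(sub$position)
    if (any(sub$position > L)) {
      stop("position ", max(sub$position), " exceeds length of ", nm,
           " (", L, ")", call. = FALSE)
    }
    fp <- integer(L); tp <- integer(L)
    fp[sub$position] <- sub$five_prime_ends
    tp[sub$position] <- sub$three_prime_ends
    out[[nm]] <- end_count_profile(nm, fp, tp)
  }
  out
}

#' Write end-count profiles as TSV
#'
#' Inverse of [read_end_counts()]; zero-count positions are written too so
#' the round trip is exact.
#' @param profiles named list of [end_count_profile].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_end_counts <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(rrna = p$rrna,
               position = seq_along(p$five_prime_ends),
               five_prime_ends = p$five_prime_ends,
               three_prime_ends = p$three_prime_ends)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive end-count profiles from read alignments (SAM/BAM)
#'
#' Each mapped, non-secondary, non-supplementary read is treated as one
#' fragment: its leftmost reference position increments the 5'-end count and
#' its rightmost (CIGAR-aware) reference position the 3'-end count, in
#' reference-strand coordinates. Unmapped/secondary/supplementary records
#' are skipped and reported in a message.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param refs named list of [rrna_reference]; alignment reference names
#'   must all be present.
#' @return named list of [end_count_profile], one per reference.
#' @export
parse_alignments <- function(path, refs) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  n_total <- length(flags)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  used <- as.character(unique(GenomicAlignments::seqnames(gal)))
  unknown <- setdiff(used, names(refs))
  if (length(unknown)) {
    stop("alignment reference(s) not among provided rRNAs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  message(sprintf("parse_alignments: %d records, %d used, %d skipped",
                  n_total, length(gal), n_total - length(gal)))
  if (length(gal) == 0L) {
    warning("no usable alignments in ", path, call. = FALSE)
  }
  sn <- as.character(GenomicAlignments::seqnames(gal))
  st <- GenomicAlignments::start(gal)
  en <- GenomicAlignments::end(gal)
  out <- list()
  for (nm in names(refs)) {
    L <- refs[[nm]]$length
    sel <- sn == nm
    if (any(sel) && max(en[sel]) > L) {
      stop("alignment beyond end of ", nm, call. = FALSE)
    }
    out[[nm]] <- end_count_profile(nm, tabulate(st[sel], L),
                                   tabulate(en[sel], L))
  }
  out
}

#' Export sites as BED6
#'
#' Converts the package's 1-based fully-closed residue coordinates to BED's
#' 0-based half-open intervals. The BED score column is the methylation
#' score scaled by 1000 and rounded (0 when no score is given).
#'
#' @param sites data frame with `rrna`, `position`, and optionally `label`
#'   and `mean_score` columns (e.g. a `site_catalog` or the output of
#'   [call_sites()]).
#' @param path output file.
#' @param strand strand character, default `"+"`.
#' @return `path`, invisibly.
#' @export
write_bed_sites <- function(sites, path, strand = "+") {
  label <- if ("label" %in% names(sites)) sites$label else
    as.character(sites$position)
  score <- if ("mean_score" %in% names(sites)) {
    ifelse(is.na(sites$mean_score), 0L, as.integer(round(sites$mean_score * 1000)))
  } else 0L
  bed <- data.frame(chrom = sites$rrna,
                    start = sites$position - 1L,
                    end = sites$position,
                    name = label,
                    score = score,
                    strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
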