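## Screening step 3: confirm motif-overlapping variants against ChIP-seq
## peak intervals.

#' Read ChIP-seq peaks from a BED3+ file
#'
#' Accepts BED with at least chrom/start/end; a fourth column is kept as the
#' peak name (otherwise names `peak_1`, ... are assigned). `track`,
#' `browser` and `#` header lines are skipped. Malformed lines -- too few
#' fields, non-integer coordinates, or `start >= end` -- are rejected with
#' their line numbers.
#'
#' @param path BED file.
#' @return Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and `name`, sorted by (contig, start).
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line(s) (fewer than 3 fields) at line ",
         paste(lineno[nf < 3L], collapse = ", "))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("non-integer BED coordinates at line ",
         paste(lineno[bad], collapse = ", "))
  }
  if (any(start >= end)) {
    stop("BED interval with start >= end at line ",
         paste(lineno[start >= end], collapse = ", "))
  }
  name <- ifelse(nf >= 4L, vapply(fields, `[`, "", 4L), NA_character_)
  name[is.na(name)] <- sprintf("peak_%d", which(is.na(name)))
  out <- data.frame(contig = vapply(fields, `[`, "", 1L),
                    start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks (or motif occurrences) to BED
#'
#' @param x Data frame with `contig`, `start`, `end` and optionally `name`,
#'   `strand` columns (0-based half-open, written natively).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else
    if ("matched_seq" %in% names(x)) x$matched_seq else "."
  lines <- paste(x$contig, x$start, x$end, name,
                 0L, if ("strand" %in% names(x)) x$strand else ".",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Confirm motif-overlapping variants against ChIP-seq peaks
#'
#' Retains candidates whose covering motif occurrence interval overlaps at
#' least one peak by >= 1 base; binding evidence is required at the *site*,
#' not merely at the variant point. Set `snp_overlap = TRUE` to switch to
#' point-in-peak semantics (the variant position itself inside a peak).
#'
#' @param candidates Data frame with columns `contig`, `pos`, and (for the
#'   default site semantics) `cov_start`/`cov_end`, the hull of covering
#'   occurrences as produced by the screening stage.
#' @param peaks Peak data frame from [read_peaks()].
#' @param snp_overlap Use the variant point instead of the occurrence
#'   interval (default `FALSE`).
#' @return The retained candidates, sorted by (contig, pos), with an added
#'   `peaks` column (comma-separated supporting peak names).
#' @export
confirm_candidates <- function(candidates, peaks, snp_overlap = FALSE) {
  if (nrow(candidates) == 0L) {
    candidates$peaks <- character(0)
    return(candidates)
  }
  if (snp_overlap) {
    qs <- candidates$pos
    qe <- candidates$pos + 1L
  } else {
    if (!all(c("cov_start", "cov_end") %in% names(candidates))) {
      stop("candidates need cov_start/cov_end columns for site-overlap semantics")
    }
    qs <- candidates$cov_start
    qe <- candidates$cov_end
  }
  hits <- vapply(seq_len(nrow(candidates)), function(i) {
    pk <- peaks[peaks$contig == candidates$contig[i], , drop = FALSE]
    if (nrow(pk) == 0L || is.na(qs[i])) return(NA_character_)
    q <- IRanges::IRanges(start = qs[i] + 1L, end = qe[i])
    s <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    ov <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    if (length(ov) == 0L) return(NA_character_)
    paste(pk$name[S4Vectors::subjectHits(ov)], collapse = ",")
  }, character(1))
  out <- candidates[!is.na(hits), , drop = FALSE]
  out$peaks <- hits[!is.na(hits)]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
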