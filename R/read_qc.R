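#' Screen repertoire reads for primers and minimum length
#'
#' A read is kept iff (i) the forward primer occurs within its first
#' `window` nt and the reverse complement of the reverse primer within its
#' last `window` nt, each within `max_primer_mm` mismatches, and (ii) its
#' untrimmed length is at least `min_length`. Primer failure is attributed
#' before length failure, so the QC counts partition the input.
#'
#' @param reads named character vector of DNA sequences (names = read ids)
#'   or the data.frame returned by [read_sequences()].
#' @param forward_primer,reverse_primer primer sequences (IUPAC allowed).
#' @param min_length minimum read length (default 400, on the untrimmed read).
#' @param max_primer_mm mismatches tolerated per primer (default 2).
#' @param window search window from each end (default 50 nt).
#' @param require_both require both primers (default TRUE); `FALSE` keeps
#'   reads carrying either.
#' @param trim remove the primers (and anything outside them) from kept
#'   reads (default FALSE).
#' @return list with `kept` (character vector like the input) and `report`
#'   (a `QcReport`: counts plus a per-read fate table).
#' @export
filter_reads <- function(reads, forward_primer, reverse_primer,
                         min_length = 400L, max_primer_mm = 2L,
                         window = 50L, require_both = TRUE, trim = FALSE) {
  if (is.data.frame(reads)) reads <- stats::setNames(reads$sequence, reads$read_id)
  stopifnot(min_length >= 0L, nzchar(forward_primer), nzchar(reverse_primer))
  forward_primer <- normalize_dna(forward_primer)
  reverse_primer <- normalize_dna(reverse_primer)
  assert_dna(forward_primer, "forward primer", iupac = TRUE)
  assert_dna(reverse_primer, "reverse primer", iupac = TRUE)
  rev_rc <- revcomp(reverse_primer)
  fate <- character(length(reads))
  kept <- character(0L)
  kept_ids <- character(0L)
  for (i in seq_along(reads)) {
    s <- reads[[i]]
    fwd_hit <- primer_hit(s, forward_primer, max_primer_mm, window, from_end = FALSE)
    rev_hit <- primer_hit(s, rev_rc, max_primer_mm, window, from_end = TRUE)
    primer_ok <- if (require_both) !is.na(fwd_hit) && !is.na(rev_hit)
                 else !is.na(fwd_hit) || !is.na(rev_hit)
    if (!primer_ok) {
      fate[i] <- "fail_primer"
    } else if (nchar(s) < min_length) {
      fate[i] <- "fail_length"
    } else {
      fate[i] <- "kept"
      out <- s
      if (trim && !is.na(fwd_hit) && !is.na(rev_hit)) {
        out <- substr(s, fwd_hit + nchar(forward_primer), rev_hit - 1L)
      }
      kept <- c(kept, out)
      kept_ids <- c(kept_ids, names(reads)[i])
    }
  }
  names(kept) <- kept_ids
  report <- structure(list(
    n_input = length(reads),
    n_kept = sum(fate == "kept"),
    n_fail_primer = sum(fate == "fail_primer"),
    n_fail_length = sum(fate == "fail_length"),
    fates = data.frame(read_id = names(reads), fate = fate,
                       stringsAsFactors = FALSE)),
    class = "QcReport")
  list(kept = kept, report = report)
}

## 1-based start of the best primer occurrence within the search window,
## or NA. IUPAC codes in the primer match their base sets.
primer_hit <- function(read, primer, max_mm, window, from_end = FALSE) {
  L <- nchar(read); k <- nchar(primer)
  if (L < k) return(NA_integer_)
  starts <- if (from_end) {
    seq.int(max(1L, L - window + 1L), L - k + 1L)
  } else {
    seq.int(1L, min(window, L - k + 1L))
  }
  pv <- chars(primer)
  best <- NA_integer_; best_mm <- max_mm + 1L
  for (s in starts) {
    sub <- chars(substr(read, s, s + k - 1L))
    mm <- sum(!iupac_match(sub, pv))
    if (mm < best_mm) { best_mm <- mm; best <- s }
  }
  if (best_mm <= max_mm) best else NA_integer_
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d input = %d kept + %d fail_primer + %d fail_length\n",
              x$n_input, x$n_kept, x$n_fail_primer, x$n_fail_length))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `QcReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$fates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
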