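#' Canonical recombination signal sequence motifs
#'
#' Heptamer `CACAGTG` and nonamer `ACAAAAACC`, the immunogenetics consensus
#' recognized by RAG1/2.
#' @name rss_motifs
#' @keywords internal
RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

#' Scan a sequence for recombination signal sequences
#'
#' Finds heptamer--spacer--nonamer arrangements on both strands within a
#' mismatch budget. The first three heptamer bases (`CAC`) are held exact by
#' default, reflecting their functional requirement for RAG cleavage; the
#' spacer may deviate from the nominal 12 or 23 nt by `spacer_tolerance`.
#' Minus-strand hits are reported on the plus axis (`position` is the
#' 0-based offset of the heptamer start as it appears on the scanned strand's
#' reverse complement, mapped back to plus coordinates of the heptamer's
#' first base interval start).
#'
#' @param sequence DNA string to scan.
#' @param spacer_class 12 or 23.
#' @param max_heptamer_mm maximum heptamer mismatches (default 1).
#' @param max_nonamer_mm maximum nonamer mismatches (default 2).
#' @param spacer_tolerance allowed spacer-length deviation (default 1).
#' @param strands `"+"`, `"-"` or `"both"`.
#' @param exact_cac hold heptamer positions 1-3 exact (default TRUE).
#' @return data.frame with columns `position`, `strand`, `heptamer`,
#'   `spacer_length`, `nonamer`, `heptamer_mm`, `nonamer_mm`, sorted by
#'   position; zero rows when the sequence is shorter than the motif span.
#' @export
find_rss <- function(sequence, spacer_class = c(12L, 23L),
                     max_heptamer_mm = 1L, max_nonamer_mm = 2L,
                     spacer_tolerance = 1L, strands = "both",
                     exact_cac = TRUE) {
  spacer_class <- as.integer(spacer_class[1L])
  stopifnot(spacer_class %in% c(12L, 23L))
  sequence <- normalize_dna(sequence)
  assert_dna(sequence, "scan sequence")
  strands <- match.arg(strands, c("both", "+", "-"))
  empty <- data.frame(position = integer(0L), strand = character(0L),
                      heptamer = character(0L), spacer_length = integer(0L),
                      nonamer = character(0L), heptamer_mm = integer(0L),
                      nonamer_mm = integer(0L), stringsAsFactors = FALSE)
  out <- list(empty)
  if (strands %in% c("both", "+")) {
    out <- c(out, list(scan_rss_strand(sequence, spacer_class, max_heptamer_mm,
                                       max_nonamer_mm, spacer_tolerance,
                                       exact_cac, "+")))
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp(sequence)
    hits <- scan_rss_strand(rc, spacer_class, max_heptamer_mm, max_nonamer_mm,
                            spacer_tolerance, exact_cac, "-")
    if (nrow(hits)) {
      ## mirror coordinate: heptamer occupies [p, p+7) on the rc strand ->
      ## [L - p - 7, L - p) on the plus axis; report its start.
      hits$position <- nchar(sequence) - hits$position - 7L
    }
    out <- c(out, list(hits))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand), , drop = FALSE]
}

## one-strand scan; coordinates 0-based on the given sequence
scan_rss_strand <- function(seq, spacer, max_h, max_n, tol, exact_cac, strand) {
  L <- nchar(seq)
  sv <- chars(seq)
  hv <- chars(RSS_HEPTAMER)
  nv <- chars(RSS_NONAMER)
  spacers <- (spacer - tol):(spacer + tol)
  rows <- list()
  min_span <- 7L + min(spacers) + 9L
  if (L < min_span) {
    return(data.frame(position = integer(0L), strand = character(0L),
                      heptamer = character(0L), spacer_length = integer(0L),
                      nonamer = character(0L), heptamer_mm = integer(0L),
                      nonamer_mm = integer(0L), stringsAsFactors = FALSE))
  }
  for (p0 in 0:(L - min_span)) {
    hseq <- sv[(p0 + 1L):(p0 + 7L)]
    if (exact_cac && !identical(hseq[1:3], hv[1:3])) next
    hmm <- sum(hseq != hv)
    if (hmm > max_h) next
    for (sp in spacers) {
      n0 <- p0 + 7L + sp
      if (n0 + 9L > L) next
      nseq <- sv[(n0 + 1L):(n0 + 9L)]
      nmm <- sum(nseq != nv)
      if (nmm > max_n) next
      rows[[length(rows) + 1L]] <- data.frame(
        position = p0, strand = strand,
        heptamer = paste(hseq, collapse = ""), spacer_length = sp,
        nonamer = paste(nseq, collapse = ""),
        heptamer_mm = hmm, nonamer_mm = nmm, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(0L), strand = character(0L),
                      heptamer = character(0L), spacer_length = integer(0L),
                      nonamer = character(0L), heptamer_mm = integer(0L),
                      nonamer_mm = integer(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export RSS hits as GFF3
#'
#' @param hits data.frame from [find_rss()].
#' @param seqid sequence name for column 1.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rss_gff3 <- function(hits, seqid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    span <- 7L + hits$spacer_length + 9L
    ## on the minus strand the RSS extends toward lower plus-axis coordinates
    from <- ifelse(hits$strand == "+", hits$position + 1L,
                   hits$position + 7L - span + 1L)
    lines <- sprintf(
      "%s\tigjunction\trecombination_signal_sequence\t%d\t%d\t.\t%s\t.\theptamer=%s;spacer=%d;nonamer=%s;mismatches=%d,%d",
      seqid, from, from + span - 1L, hits$strand,
      hits$heptamer, hits$spacer_length, hits$nonamer,
      hits$heptamer_mm, hits$nonamer_mm)
    writeLines(lines, con)
  }
  invisible(path)
}
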