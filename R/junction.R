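#' Locate the CDR3 of an annotated read
#'
#' The CDR3 is the read segment strictly between the conserved second-Cys
#' codon (the `YYC` cysteine closing FR3) and the conserved Trp/Phe codon of
#' the J FR4 motif (`WGXG` for heavy chains, `FGXG` for light chains) --
#' both anchors exclusive. Anchors are placed by projecting the germline
#' anchor codons through the V and J alignments, so a somatic mutation
#' inside an anchor codon does not move the interval; when projection is
#' impossible the read is scanned for the motifs directly, allowing one
#' amino-acid mismatch at the non-critical positions (the C and the W/F
#' themselves are held fixed).
#'
#' @param read DNA string.
#' @param v_call,j_call `SegmentCall`s from [assign_v()] / [assign_j()]
#'   (either may be `NULL`, forcing the motif-scan fallback).
#' @param germline_set the `GermlineSet` used for assignment.
#' @return a `Cdr3` list: `nt_start`, `nt_end` (0-based half-open, anchors
#'   excluded), `nt_sequence`, `aa_sequence` (NA when out of frame),
#'   `anchor_c_position`, `anchor_wf_position` (0-based codon starts),
#'   `anchor_mismatches`, `in_frame`; or `NULL` with attribute when no
#'   anchor is locatable (the record is flagged `cdr3_missing` upstream).
#' @export
locate_cdr3 <- function(read, v_call, j_call, germline_set) {
  c_start <- NA_integer_; w_start <- NA_integer_; mism <- 0L
  if (!is.null(v_call)) {
    v_gene <- germline_set$genes[[v_call$best$gene_id]]
    fr3_end <- v_gene$region_bounds$FR3[2]           # 0-based end of FR3
    co <- v_call$best$core_offset
    ## first nt of the Cys codon, 1-based in core coordinates
    cys_nt <- fr3_end - 2L - co
    hit <- project_position(v_call$best$map, cys_nt)
    if (!is.na(hit)) c_start <- hit - 1L             # 0-based on read
  }
  if (!is.null(j_call)) {
    j_gene <- germline_set$genes[[j_call$best$gene_id]]
    jc <- classify_j_gene(j_gene)
    if (!is.na(jc$frame)) {
      anchor_nt <- jc$frame + (jc$motif_aa_start - 1L) * 3L + 1L
      hit <- project_position(j_call$best$map, anchor_nt)
      if (!is.na(hit)) w_start <- hit - 1L
    }
  }
  locus <- germline_set$locus
  wf_expected <- if (locus == "IGH") "W" else "F"
  if (is.na(c_start) || is.na(w_start)) {
    scan <- scan_cdr3_motifs(read, wf_expected)
    if (is.na(c_start)) c_start <- scan$c_start
    if (is.na(w_start)) w_start <- scan$w_start
  }
  if (is.na(c_start) || is.na(w_start) || w_start <= c_start + 2L) {
    return(NULL)
  }
  nt_start <- c_start + 3L
  nt_end <- w_start
  nt <- substr(read, nt_start + 1L, nt_end)
  in_frame <- nchar(nt) %% 3L == 0L
  aa <- if (in_frame && nchar(nt) > 0L) translate_frame(nt, 0L) else NA_character_
  c_aa <- translate_frame(substr(read, c_start + 1L, c_start + 3L), 0L)
  w_aa <- translate_frame(substr(read, w_start + 1L, w_start + 3L), 0L)
  mism <- sum(c(c_aa != "C", w_aa != wf_expected))
  structure(list(nt_start = nt_start, nt_end = nt_end, nt_sequence = nt,
                 aa_sequence = aa, anchor_c_position = c_start,
                 anchor_wf_position = w_start, anchor_mismatches = mism,
                 in_frame = in_frame),
            class = "Cdr3")
}

## motif-scan fallback: last YYC-like codon and the first downstream
## WGXG/FGXG-like motif in the same frame. C and W/F are fixed; one
## mismatch allowed among the non-critical residues.
scan_cdr3_motifs <- function(read, wf = "W") {
  best <- list(c_start = NA_integer_, w_start = NA_integer_)
  for (f in 0:2) {
    aa <- chars(translate_frame(read, f))
    n <- length(aa)
    if (n < 8L) next
    c_idx <- which(aa == "C")
    c_idx <- c_idx[c_idx >= 3L]
    c_ok <- c_idx[vapply(c_idx, function(i)
      sum(aa[c(i - 2L, i - 1L)] != "Y") <= 1L, logical(1L))]
    if (!length(c_ok)) next
    w_idx <- which(aa == wf)
    w_ok <- w_idx[vapply(w_idx, function(i)
      i + 3L <= n && sum(aa[c(i + 1L, i + 3L)] != "G") <= 1L, logical(1L))]
    for (ci in rev(c_ok)) {
      wi <- w_ok[w_ok > ci + 1L]
      if (length(wi)) {
        return(list(c_start = f + (ci - 1L) * 3L,
                    w_start = f + (wi[1L] - 1L) * 3L))
      }
    }
  }
  best
}

#' Decompose a V(D)J junction into germline-retained, P and N nucleotides
#'
#' Attribution rules (deterministic, testable against exhaustive
#' enumeration): (1) the V attribution is extended rightward from the FR3
#' alignment end by the longest exact match to the germline V 3'
#' continuation, and the J attribution symmetrically leftward -- maximal
#' templated attribution, with bases claimable by both resolved in favour
#' of V; (2) trims are the germline bases beyond the retained ends;
#' (3) P nucleotides are recognized only at untrimmed ends, as the longest
#' run (capped at `max_p_len`) of insert bases equal to the reverse
#' complement of the terminal retained bases; (4) on heavy chains the best
#' exact D match of at least `min_d_match` nt is attributed with its own
#' trims and P rules; (5) all remaining insert bases are N. Mismatches
#' never extend templated attribution (somatic mutation inside the junction
#' is treated as N).
#'
#' @param read DNA string.
#' @param germline_set the `GermlineSet`.
#' @param v_call,j_call `SegmentCall`s.
#' @param max_p_len P-nucleotide cap (default 4).
#' @param min_d_match minimum exact D match (default 5); D search is
#'   skipped for light-chain sets.
#' @return a `JunctionDecomposition` list; the concatenation invariant
#'   (retained V + p1 + n1 \[+ p_d5 + D + p_d3 + n2\] + p2 + retained J ==
#'   observed junction) is asserted before returning.
#' @export
decompose_junction <- function(read, germline_set, v_call, j_call,
                               max_p_len = 4L, min_d_match = 5L) {
  v_gene <- germline_set$genes[[v_call$best$gene_id]]
  j_gene <- germline_set$genes[[j_call$best$gene_id]]
  vx <- extend_v_attribution(read, v_gene, v_call)
  jx <- extend_j_attribution(read, j_gene, j_call, floor_read_pos = vx$read_end)
  insert <- substr(read, vx$read_end + 1L, jx$read_start)
  glen_v <- nchar(v_gene$nt_sequence)
  v_del <- vx$v_deletion
  j_del <- jx$j_deletion

  p1 <- ""
  if (v_del == 0L && nchar(insert) > 0L) {
    p1 <- longest_p(insert, v_gene$nt_sequence, max_p_len, side = "v")
  }
  rest <- substr(insert, nchar(p1) + 1L, nchar(insert))
  p2 <- ""
  if (j_del == 0L && nchar(rest) > 0L) {
    p2 <- longest_p(rest, j_gene$nt_sequence, max_p_len, side = "j")
  }
  middle <- substr(rest, 1L, nchar(rest) - nchar(p2))

  d_id <- NA_character_; retained_d <- ""
  d_del5 <- NA_integer_; d_del3 <- NA_integer_
  p_d5 <- ""; p_d3 <- ""; n1 <- middle; n2 <- ""
  ds <- genes_of_type(germline_set, "D")
  if (length(ds) && nchar(middle) >= min_d_match) {
    dmatch <- match_d_in_window(middle, ds, min_d_match)
    if (!is.null(dmatch)) {
      d_gene <- germline_set$genes[[dmatch$best$gene_id]]
      d_id <- d_gene$gene_id
      a0 <- dmatch$best$read_interval[1]      # 0-based within `middle`
      a1 <- dmatch$best$read_interval[2]
      d_del5 <- dmatch$best$germline_interval[1]
      d_del3 <- nchar(d_gene$nt_sequence) - dmatch$best$germline_interval[2]
      retained_d <- substr(middle, a0 + 1L, a1)
      pre <- substr(middle, 1L, a0)
      post <- substr(middle, a1 + 1L, nchar(middle))
      if (d_del5 == 0L && nchar(pre) > 0L) {
        p_d5 <- longest_p_suffix(pre, d_gene$nt_sequence, max_p_len)
      }
      if (d_del3 == 0L && nchar(post) > 0L) {
        p_d3 <- longest_p(post, d_gene$nt_sequence, max_p_len, side = "v")
      }
      n1 <- substr(pre, 1L, nchar(pre) - nchar(p_d5))
      n2 <- substr(post, nchar(p_d3) + 1L, nchar(post))
    }
  }

  ## retained lengths inside the CDR3 (beyond FR3 / before the J anchor)
  fr3_end <- v_gene$region_bounds$FR3[2]
  retained_v_len <- max(0L, vx$germline_end - fr3_end)
  jc <- classify_j_gene(j_gene)
  retained_j_len <- if (!is.na(jc$frame)) {
    anchor0 <- jc$frame + (jc$motif_aa_start - 1L) * 3L
    max(0L, anchor0 - jx$germline_start)
  } else NA_integer_

  dec <- structure(list(
    v_gene = v_gene$gene_id, j_gene = j_gene$gene_id, d_gene = d_id,
    v_deletion = v_del, j_deletion = j_del,
    p1 = p1, n1 = n1,
    p_d5 = p_d5, d_deletion_5p = d_del5, retained_d = retained_d,
    d_deletion_3p = d_del3, p_d3 = p_d3, n2 = n2, p2 = p2,
    retained_v_len = retained_v_len, retained_j_len = retained_j_len,
    v_read_end = vx$read_end, j_read_start = jx$read_start),
    class = "JunctionDecomposition")

  ## concatenation invariant over the insert window
  rebuilt <- paste0(p1, n1, p_d5, retained_d, p_d3, n2, p2)
  if (!identical(rebuilt, insert)) {
    stop("internal error: junction reconstruction failed for read")
  }
  ## P legality
  if ((nchar(p1) > 0L && v_del != 0L) || (nchar(p2) > 0L && j_del != 0L)) {
    stop("internal error: P nucleotide adjacent to a trimmed end")
  }
  dec
}

## longest insert prefix equal to the reverse complement of the germline
## terminal bases. side = "v": germline 3' end mirrored into the insert;
## side = "j": germline 5' start mirrored (prefix form used for p_d3 too).
longest_p <- function(insert, germline, max_p_len, side = c("v", "j")) {
  side <- match.arg(side)
  gl <- nchar(germline)
  kmax <- min(max_p_len, nchar(insert), gl)
  best <- ""
  for (k in seq_len(kmax)) {
    expect <- if (side == "v") revcomp(substr(germline, gl - k + 1L, gl))
              else revcomp(substr(germline, 1L, k))
    got <- if (side == "v") substr(insert, 1L, k)
           else substr(insert, nchar(insert) - k + 1L, nchar(insert))
    if (identical(got, expect)) best <- got else break
  }
  best
}

## longest insert suffix equal to the revcomp of the germline 5' start
## (P adjacent to an untrimmed D 5' end)
longest_p_suffix <- function(insert, germline, max_p_len) {
  kmax <- min(max_p_len, nchar(insert), nchar(germline))
  best <- ""
  for (k in seq_len(kmax)) {
    expect <- revcomp(substr(germline, 1L, k))
    got <- substr(insert, nchar(insert) - k + 1L, nchar(insert))
    if (identical(got, expect)) best <- got else break
  }
  best
}

#' Junction and CDR3 length statistics
#'
#' Histograms plus mean and population standard deviation (denominator n)
#' for V/J trims, P and N lengths, and CDR3 nucleotide/amino-acid lengths.
#' Records without a located CDR3 are excluded and counted.
#'
#' @param records list of annotated records (see [annotate_reads()]).
#' @return list of per-quantity tables plus `n`, `n_cdr3_missing` and a
#'   `summary` data.frame of mean +/- SD.
#' @export
junction_length_stats <- function(records) {
  has_cdr3 <- vapply(records, function(r) !is.null(r$cdr3), logical(1L))
  with_dec <- Filter(function(r) !is.null(r$junction_decomposition), records)
  quantity <- function(f) vapply(with_dec, f, numeric(1L))
  vals <- list(
    v_deletion = quantity(function(r) r$junction_decomposition$v_deletion),
    j_deletion = quantity(function(r) r$junction_decomposition$j_deletion),
    p1_length = quantity(function(r) nchar(r$junction_decomposition$p1)),
    p2_length = quantity(function(r) nchar(r$junction_decomposition$p2)),
    n_length = quantity(function(r) nchar(r$junction_decomposition$n1) +
                          nchar(r$junction_decomposition$n2)),
    cdr3_nt_length = vapply(Filter(function(r) !is.null(r$cdr3), records),
                            function(r) nchar(r$cdr3$nt_sequence), numeric(1L)),
    cdr3_aa_length = vapply(Filter(function(r) !is.null(r$cdr3) && r$cdr3$in_frame,
                                   records),
                            function(r) nchar(r$cdr3$aa_sequence), numeric(1L)))
  tables <- lapply(vals, function(v) {
    if (!length(v)) return(data.frame(value = integer(0L), count = integer(0L)))
    tb <- table(v)
    data.frame(value = as.integer(names(tb)), count = as.integer(tb))
  })
  summary <- data.frame(
    quantity = names(vals),
    n = vapply(vals, length, integer(1L)),
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, numeric(1L)),
    sd = vapply(vals, pop_sd, numeric(1L)),
    min = vapply(vals, function(v) if (length(v)) min(v) else NA_real_, numeric(1L)),
    max = vapply(vals, function(v) if (length(v)) max(v) else NA_real_, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tables = tables, summary = summary,
       n = length(records), n_cdr3_missing = sum(!has_cdr3))
}
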