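# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; the oracles deliberately reimplement the checked
# operations by brute force.

toy_igh <- make_toy_germline()
toy_igk <- make_toy_germline(locus = "IGK")

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## ---- RSS oracle: naive sliding-window Hamming scan ----------------------

naive_rss_scan <- function(sequence, spacer, max_h = 1L, max_n = 2L,
                           tol = 1L, exact_cac = TRUE) {
  scan1 <- function(seq, strand) {
    L <- nchar(seq)
    hits <- NULL
    for (p in 0:max(0L, L - 1L)) {
      if (p + 7L > L) next
      hep <- substr(seq, p + 1L, p + 7L)
      if (exact_cac && substr(hep, 1L, 3L) != "CAC") next
      hmm <- sum(strsplit(hep, "")[[1L]] != strsplit("CACAGTG", "")[[1L]])
      if (hmm > max_h) next
      for (sp in (spacer - tol):(spacer + tol)) {
        n0 <- p + 7L + sp
        if (n0 + 9L > L) next
        non <- substr(seq, n0 + 1L, n0 + 9L)
        nmm <- sum(strsplit(non, "")[[1L]] != strsplit("ACAAAAACC", "")[[1L]])
        if (nmm > max_n) next
        hits <- rbind(hits, data.frame(position = p, strand = strand,
                                       spacer_length = sp))
      }
    }
    hits
  }
  fwd <- scan1(sequence, "+")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "")[[1L]]),
              collapse = "")
  rev <- scan1(rc, "-")
  if (!is.null(rev)) rev$position <- nchar(sequence) - rev$position - 7L
  out <- rbind(fwd, rev)
  if (is.null(out)) return(data.frame(position = integer(0L),
                                      strand = character(0L),
                                      spacer_length = integer(0L)))
  out[order(out$position, out$strand), , drop = FALSE]
}

## ---- junction micro-instances and enumeration oracle --------------------

## toy 20-nt V (core = first 12 nt, 8-nt junction-forming tail) and 20-nt J
make_micro_set <- function(v_seq, j_seq) {
  v <- germline_gene("MICROV", "IGK", "V", v_seq,
                     region_bounds = list(FR1 = c(0L, 6L), FR3 = c(6L, 12L)))
  j <- germline_gene("MICROJ", "IGK", "J", j_seq)
  germline_set(list(v, j), locus = "IGK")
}

## hand-built SegmentCall anchored on an exactly matching block
manual_call <- function(gene_id, g_from, g_to, r_from, gene_seq, read,
                        core_offset = 0L) {
  map <- data.frame(
    pattern_pos = (g_from:g_to) - core_offset,
    subject_pos = r_from:(r_from + g_to - g_from),
    pattern_base = strsplit(substr(gene_seq, g_from, g_to), "")[[1L]],
    subject_base = strsplit(substr(read, r_from, r_from + g_to - g_from),
                            "")[[1L]],
    stringsAsFactors = FALSE)
  igjunction:::new_segment_call(
    igjunction:::make_segment_alignment(gene_id, map, g_to - g_from + 1L,
                                        core_offset),
    gene_id)
}

## decompose a micro read (V' + insert + J') through the package path
micro_decompose <- function(set, v_del, j_del, insert, max_p_len = 4L) {
  v_seq <- set$genes$MICROV$nt_sequence
  j_seq <- set$genes$MICROJ$nt_sequence
  v_part <- substr(v_seq, 1L, nchar(v_seq) - v_del)
  j_part <- substr(j_seq, j_del + 1L, nchar(j_seq))
  read <- paste0(v_part, insert, j_part)
  v_call <- manual_call("MICROV", 1L, 12L, 1L, v_seq, read)
  ## J anchored on its always-intact last 8 bases
  j_anchor_g <- nchar(j_seq) - 7L
  j_anchor_r <- nchar(read) - 7L
  j_call <- manual_call("MICROJ", j_anchor_g, nchar(j_seq), j_anchor_r,
                        j_seq, read)
  dec <- decompose_junction(read, set, v_call, j_call, max_p_len = max_p_len)
  list(read = read, dec = dec)
}

## independent enumeration oracle: every consistent split, then
## max templated attribution (ties to V), then max P at untrimmed ends
junction_oracle <- function(set, v_del, j_del, insert, max_p_len = 4L) {
  v_seq <- set$genes$MICROV$nt_sequence
  j_seq <- set$genes$MICROJ$nt_sequence
  vl <- nchar(v_seq); jl <- nchar(j_seq)
  v_part <- substr(v_seq, 1L, vl - v_del)
  j_part <- substr(j_seq, j_del + 1L, jl)
  read <- paste0(v_part, insert, j_part)
  L <- nchar(read)
  core_end <- 12L
  best <- NULL
  for (a in 0:(vl - core_end)) {             # V bases attributed past the core
    v_end_g <- core_end + a
    if (core_end + a > L) break
    if (substr(read, core_end + 1L, core_end + a) !=
        substr(v_seq, core_end + 1L, v_end_g)) next
    for (g in 1:(jl + 1L)) {                 # first retained germline J base
      keep <- jl - g + 1L
      if (keep > L - core_end - a) next
      if (keep > 0L &&
          substr(read, L - keep + 1L, L) != substr(j_seq, g, jl)) next
      cand <- list(a = a, g = g, templated = a + keep)
      if (is.null(best) || cand$templated > best$templated ||
          (cand$templated == best$templated && cand$a > best$a)) {
        best <- cand
      }
    }
  }
  a <- best$a; g <- best$g
  o_v_del <- vl - core_end - a
  o_j_del <- g - 1L
  ins <- substr(read, core_end + a + 1L, L - (jl - g + 1L))
  ## maximal P at untrimmed ends, V side first
  p1 <- ""
  if (o_v_del == 0L) {
    for (k in seq_len(min(max_p_len, nchar(ins)))) {
      exp_p <- paste(rev(strsplit(chartr("ACGT", "TGCA",
        substr(v_seq, vl - k + 1L, vl)), "")[[1L]]), collapse = "")
      if (substr(ins, 1L, k) == exp_p) p1 <- substr(ins, 1L, k) else break
    }
  }
  rest <- substr(ins, nchar(p1) + 1L, nchar(ins))
  p2 <- ""
  if (o_j_del == 0L) {
    for (k in seq_len(min(max_p_len, nchar(rest)))) {
      exp_p <- paste(rev(strsplit(chartr("ACGT", "TGCA",
        substr(j_seq, 1L, k)), "")[[1L]]), collapse = "")
      if (substr(rest, nchar(rest) - k + 1L, nchar(rest)) == exp_p)
        p2 <- exp_p else break
    }
  }
  n <- substr(rest, 1L, nchar(rest) - nchar(p2))
  list(v_deletion = o_v_del, j_deletion = o_j_del, p1 = p1, n = n, p2 = p2,
       ambiguous = !(o_v_del == v_del && o_j_del == j_del &&
                       p1 == "" && p2 == "" && n == insert))
}

## all insert strings up to a given length
all_inserts <- function(max_len) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), l))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

## ---- annotation vs simulator truth --------------------------------------

truth_comparison <- function(records, truth) {
  data.frame(
    v_ok = vapply(seq_along(records), function(i)
      !is.null(records[[i]]$v_call) &&
        records[[i]]$v_call$best$gene_id == truth$v_call[i], logical(1L)),
    j_ok = vapply(seq_along(records), function(i)
      !is.null(records[[i]]$j_call) &&
        records[[i]]$j_call$best$gene_id == truth$j_call[i], logical(1L)),
    cdr3_ok = vapply(seq_along(records), function(i) {
      r <- records[[i]]
      !is.null(r$cdr3) && !is.na(truth$cdr3_end[i]) &&
        r$cdr3$nt_start == truth$cdr3_start[i] &&
        r$cdr3$nt_end == truth$cdr3_end[i]
    }, logical(1L)))
}
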