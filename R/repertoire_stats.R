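#' Segment-usage frequencies
#'
#' One count per read, without clonotype deduplication. At `level = "gene"`
#' ambiguous (tied) calls are counted under a combined tied-call label
#' (ids joined with `,`); at `level = "clan"` they collapse into their clan
#' when the tied genes share one. Percentages are over assigned reads;
#' unassigned reads are reported separately, never silently dropped.
#'
#' @param records annotated records (see [annotate_reads()]).
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param level `"gene"` or `"clan"` (clan applies to V only).
#' @param germline_set required at clan level (for clan membership).
#' @param dedup drop duplicate read sequences first (default FALSE,
#'   mirroring repertoire counting without removing repeated reads).
#' @return a `UsageTable`: data.frame (`label`, `count`, `percent`) plus
#'   attributes `n_assigned`, `n_unassigned`, `level`.
#' @export
usage_frequencies <- function(records, segment = c("V", "D", "J"),
                              level = c("gene", "clan"), germline_set = NULL,
                              dedup = FALSE) {
  segment <- match.arg(segment)
  level <- match.arg(level)
  if (dedup) {
    seqs <- vapply(records, function(r) r$sequence, character(1L))
    records <- records[!duplicated(seqs)]
  }
  slot <- c(V = "v_call", D = "d_call", J = "j_call")[[segment]]
  labels <- vapply(records, function(r) {
    call <- r[[slot]]
    if (is.null(call)) return(NA_character_)
    if (level == "clan" && segment == "V") {
      if (!is.null(germline_set)) {
        cl <- unique(vapply(call$ties, function(id)
          germline_set$genes[[id]]$clan, character(1L)))
        if (length(cl) == 1L && !is.na(cl)) return(cl)
      }
      if (!is.na(call$clan)) return(call$clan)
      return(paste(sort(call$ties), collapse = ","))
    }
    if (call$ambiguous) paste(sort(call$ties), collapse = ",")
    else call$best$gene_id
  }, character(1L))
  assigned <- labels[!is.na(labels)]
  tb <- sort(table(assigned), decreasing = TRUE)
  out <- data.frame(label = names(tb), count = as.integer(tb),
                    percent = if (length(tb)) 100 * as.integer(tb) / length(assigned)
                              else numeric(0L),
                    stringsAsFactors = FALSE)
  attr(out, "n_assigned") <- length(assigned)
  attr(out, "n_unassigned") <- sum(is.na(labels))
  attr(out, "level") <- level
  attr(out, "segment") <- segment
  class(out) <- c("UsageTable", "data.frame")
  out
}

#' V(D)J combination table
#'
#' Exhaustive counts of (V, D, J) label triples (pairs for light chains),
#' sorted descending -- the tabular equivalent of a Sankey diagram.
#'
#' @param records annotated records.
#' @param level `"gene"` or `"clan"` for the V label.
#' @param germline_set required at clan level.
#' @return data.frame with `v_label`, (`d_label`,) `j_label`, `count`.
#' @export
combination_table <- function(records, level = c("gene", "clan"),
                              germline_set = NULL) {
  level <- match.arg(level)
  lab <- function(call, clan_level = FALSE) {
    if (is.null(call)) return(NA_character_)
    if (clan_level && !is.na(call$clan)) return(call$clan)
    if (call$ambiguous) paste(sort(call$ties), collapse = ",")
    else call$best$gene_id
  }
  has_d <- any(vapply(records, function(r) !is.null(r$d_call), logical(1L)))
  rows <- data.frame(
    v_label = vapply(records, function(r) lab(r$v_call, level == "clan"),
                     character(1L)),
    j_label = vapply(records, function(r) lab(r$j_call), character(1L)),
    stringsAsFactors = FALSE)
  if (has_d) {
    rows$d_label <- vapply(records, function(r) {
      l <- lab(r$d_call); if (is.na(l)) "none" else l
    }, character(1L))
    rows <- rows[, c("v_label", "d_label", "j_label")]
  }
  rows <- rows[stats::complete.cases(rows), , drop = FALSE]
  if (!nrow(rows)) {
    rows$count <- integer(0L)
    return(rows)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(rows))), rows, sum)
  agg[order(-agg$count, agg$v_label), , drop = FALSE]
}

#' CDR3 segment-contribution statistics
#'
#' Mean and population SD of the nucleotide lengths that the retained V 3'
#' end, the retained D (heavy chains) and the retained J 5' end contribute
#' to the CDR3, plus the CDR3 nucleotide length itself. Records without a
#' D call are excluded from the D statistic and reported separately.
#'
#' @param records annotated records with junction decompositions.
#' @return data.frame of `quantity`, `n`, `mean`, `sd`; attribute
#'   `n_no_d` counts records lacking a D call.
#' @export
segment_contribution_stats <- function(records) {
  recs <- Filter(function(r) !is.null(r$junction_decomposition) &&
                   !is.null(r$cdr3), records)
  gv <- function(f) vapply(recs, f, numeric(1L))
  v_len <- gv(function(r) r$junction_decomposition$retained_v_len)
  j_len <- gv(function(r) r$junction_decomposition$retained_j_len)
  cdr3_len <- gv(function(r) nchar(r$cdr3$nt_sequence))
  d_len <- vapply(Filter(function(r) !is.na(r$junction_decomposition$d_gene), recs),
                  function(r) nchar(r$junction_decomposition$retained_d),
                  numeric(1L))
  n_no_d <- sum(vapply(recs, function(r)
    is.na(r$junction_decomposition$d_gene), logical(1L)))
  row <- function(q, v) data.frame(quantity = q, n = length(v),
                                   mean = if (length(v)) mean(v) else NA_real_,
                                   sd = pop_sd(v), stringsAsFactors = FALSE)
  out <- rbind(row("retained_v", v_len), row("retained_d", d_len),
               row("retained_j", j_len), row("cdr3_nt", cdr3_len))
  attr(out, "n_no_d") <- n_no_d
  out
}
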