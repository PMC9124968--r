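## Alignment scoring used throughout: match +1, mismatch -1,
## gap open -4, gap extend -1 (deterministic, order-independent best hit).
.igj_cache <- new.env(parent = emptyenv())

subst_mat <- function() {
  if (is.null(.igj_cache$mat)) {
    .igj_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  }
  .igj_cache$mat
}

## coordinate map of a single pairwise alignment: one row per aligned column
## with 1-based positions in the original pattern/subject (NA opposite gaps).
alignment_map <- function(aln) {
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))
  pstart <- BiocGenerics::start(Biostrings::pattern(aln))
  sstart <- BiocGenerics::start(Biostrings::subject(aln))
  pp <- cumsum(p != "-") + pstart - 1L
  sp <- cumsum(s != "-") + sstart - 1L
  pp[p == "-"] <- NA_integer_
  sp[s == "-"] <- NA_integer_
  data.frame(pattern_pos = pp, subject_pos = sp,
             pattern_base = p, subject_base = s, stringsAsFactors = FALSE)
}

## Map for alignment i of a vectorized PairwiseAlignments object.
## Fast path: ungapped alignments (the overwhelming case for substitution-
## only reads) are reconstructed directly from the start/end accessors and
## the original strings, avoiding costly aligned-string extraction.
fast_map <- function(alns, i, pat_str, subj_str) {
  ni <- Biostrings::nindel(alns)
  ins <- Biostrings::insertion(ni)
  del <- Biostrings::deletion(ni)
  if (ins[i, 1L] == 0L && del[i, 1L] == 0L) {
    ps <- BiocGenerics::start(Biostrings::pattern(alns))[i]
    pe <- BiocGenerics::end(Biostrings::pattern(alns))[i]
    ss <- BiocGenerics::start(Biostrings::subject(alns))[i]
    data.frame(pattern_pos = ps:pe, subject_pos = ss:(ss + pe - ps),
               pattern_base = chars(substr(pat_str, ps, pe)),
               subject_base = chars(substr(subj_str, ss, ss + pe - ps)),
               stringsAsFactors = FALSE)
  } else {
    alignment_map(alns[i])
  }
}

## project a 1-based pattern position to the subject (NA when unalignable)
project_position <- function(map, pattern_pos) {
  hit <- map$subject_pos[match(pattern_pos, map$pattern_pos)]
  if (length(hit) == 0L) NA_integer_ else hit
}

make_segment_alignment <- function(gene_id, map, score, core_offset = 0L) {
  aligned <- !is.na(map$pattern_pos) & !is.na(map$subject_pos)
  mm <- aligned & map$pattern_base != map$subject_base
  mutated <- data.frame(
    germline_position = map$pattern_pos[mm] - 1L + core_offset,
    germline_base = map$pattern_base[mm],
    read_base = map$subject_base[mm], stringsAsFactors = FALSE)
  glen <- sum(!is.na(map$pattern_pos))
  structure(list(
    gene_id = gene_id,
    read_interval = c(min(map$subject_pos, na.rm = TRUE) - 1L,
                      max(map$subject_pos, na.rm = TRUE)),
    germline_interval = c(min(map$pattern_pos, na.rm = TRUE) - 1L + core_offset,
                          max(map$pattern_pos, na.rm = TRUE) + core_offset),
    score = score,
    percent_identity = 1 - nrow(mutated) / glen,
    mutated_positions = mutated,
    map = map, core_offset = core_offset),
    class = "SegmentAlignment")
}

new_segment_call <- function(best, ties, clan = NA_character_) {
  structure(list(best = best, ties = ties, clan = clan,
                 ambiguous = length(ties) > 1L),
            class = "SegmentCall")
}

#' Assign the template germline V gene of a read
#'
#' Aligns each candidate germline V's FR1-FR3 core globally against the read
#' (global in the germline, local in the read) and keeps the best score.
#' Score ties within `tie_margin` are reported as an ambiguous, clan-level
#' call. Mutated positions are recorded over FR1-FR3 only (substitutions;
#' positions are 0-based on the germline gene).
#'
#' @param read DNA string.
#' @param germline_set a `GermlineSet` with at least one V carrying
#'   FR1-FR3 bounds.
#' @param tie_margin score difference treated as a tie (default 0).
#' @param min_score minimum alignment score for a call (default 50).
#' @param functional_only restrict candidates to genes classified (or
#'   designed) functional when functionality labels are present
#'   (default FALSE: use every V with bounds).
#' @return a `SegmentCall` (fields `best`, `ties`, `clan`, `ambiguous`) or
#'   `NULL` when no alignment reaches `min_score`.
#' @export
assign_v <- function(read, germline_set, tie_margin = 0, min_score = 50,
                     functional_only = FALSE) {
  vs <- genes_of_type(germline_set, "V")
  vs <- Filter(function(g) !is.null(v_core_seq(g)), vs)
  if (functional_only) {
    vs <- Filter(function(g) is.na(g$functionality) ||
                   g$functionality == "functional", vs)
  }
  if (!length(vs)) stop("germline set has no V gene with FR1-FR3 bounds")
  vs <- vs[order(names(vs))]  # canonical candidate order
  cores <- vapply(vs, v_core_seq, character(1L))
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(cores), Biostrings::DNAString(read),
    type = "global-local", substitutionMatrix = subst_mat(),
    gapOpening = 4, gapExtension = 1)
  scores <- BiocGenerics::score(alns)
  if (max(scores) < min_score) return(NULL)
  best_i <- which.max(scores)
  ties <- names(vs)[scores >= scores[best_i] - tie_margin]
  gene <- vs[[best_i]]
  core_offset <- gene$region_bounds$FR1[1]
  best <- make_segment_alignment(
    gene$gene_id, fast_map(alns, best_i, cores[[best_i]], read),
    scores[best_i], core_offset)
  clan <- if (length(ties) > 1L) {
    cl <- unique(vapply(vs[ties], function(g) g$clan, character(1L)))
    if (length(cl) == 1L && !is.na(cl)) cl else NA_character_
  } else gene$clan
  new_segment_call(best, ties, clan)
}

#' Assign the template germline J gene of a read
#'
#' Aligns each germline J locally against the read downstream of the V
#' alignment end; tie semantics as in [assign_v()].
#'
#' @param read DNA string.
#' @param germline_set a `GermlineSet`.
#' @param v_call the `SegmentCall` from [assign_v()] (or `NULL` to scan the
#'   whole read).
#' @param tie_margin score difference treated as a tie (default 0).
#' @param min_score minimum local alignment score (default 15).
#' @return a `SegmentCall` or `NULL` (unassigned).
#' @export
assign_j <- function(read, germline_set, v_call = NULL, tie_margin = 0,
                     min_score = 15) {
  js <- genes_of_type(germline_set, "J")
  if (!length(js)) stop("germline set has no J gene")
  js <- js[order(names(js))]
  offset <- if (!is.null(v_call)) v_call$best$read_interval[2] else 0L
  suffix <- substr(read, offset + 1L, nchar(read))
  if (!nzchar(suffix)) return(NULL)
  jseqs <- vapply(js, `[[`, character(1L), "nt_sequence")
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(jseqs), Biostrings::DNAString(suffix),
    type = "local", substitutionMatrix = subst_mat(),
    gapOpening = 4, gapExtension = 1)
  scores <- BiocGenerics::score(alns)
  if (max(scores) < min_score) return(NULL)
  best_i <- which.max(scores)
  ties <- names(js)[scores >= scores[best_i] - tie_margin]
  map <- fast_map(alns, best_i, jseqs[[best_i]], suffix)
  map$subject_pos <- map$subject_pos + offset  # back to read coordinates
  best <- make_segment_alignment(js[[best_i]]$gene_id, map, scores[best_i])
  new_segment_call(best, ties)
}

#' Assign the template germline D gene inside the junction (heavy chain)
#'
#' Searches the junction window between the maximal templated V attribution
#' and the maximal templated J attribution for the longest exact match to
#' any germline D, requiring at least `min_d_match` nt.
#'
#' @param read DNA string.
#' @param germline_set a `GermlineSet` (locus IGH).
#' @param v_call,j_call `SegmentCall`s from [assign_v()] / [assign_j()].
#' @param min_d_match minimum exact match length (default 5).
#' @return a `SegmentCall` whose `best` carries `read_interval` (on the
#'   read) and `germline_interval` (on the D), or `NULL` when no D reaches
#'   the threshold.
#' @export
assign_d <- function(read, germline_set, v_call, j_call, min_d_match = 5L) {
  ds <- genes_of_type(germline_set, "D")
  if (!length(ds)) return(NULL)
  v_gene <- germline_set$genes[[v_call$best$gene_id]]
  j_gene <- germline_set$genes[[j_call$best$gene_id]]
  vx <- extend_v_attribution(read, v_gene, v_call)
  jx <- extend_j_attribution(read, j_gene, j_call, floor_read_pos = vx$read_end)
  window <- substr(read, vx$read_end + 1L, jx$read_start)
  match_d_in_window(window, ds, min_d_match, read_offset = vx$read_end)
}

## shared: best exact D match within a window. read_offset converts window
## coordinates to read coordinates (0-based half-open).
match_d_in_window <- function(window, ds, min_d_match, read_offset = 0L) {
  if (!nzchar(window)) return(NULL)
  ds <- ds[order(names(ds))]
  best <- NULL
  for (g in ds) {
    lcs <- longest_common_substring(window, g$nt_sequence)
    if (lcs$len >= min_d_match && (is.null(best) || lcs$len > best$len)) {
      best <- c(lcs, list(gene = g))
    }
  }
  if (is.null(best)) return(NULL)
  aln <- structure(list(
    gene_id = best$gene$gene_id,
    read_interval = c(read_offset + best$a_start - 1L,
                      read_offset + best$a_start - 1L + best$len),
    germline_interval = c(best$b_start - 1L, best$b_start - 1L + best$len),
    score = best$len, percent_identity = 1, mutated_positions = NULL,
    map = NULL, core_offset = 0L), class = "SegmentAlignment")
  new_segment_call(aln, best$gene$gene_id)
}

## maximal templated V attribution: walk rightward from the FR3 core
## alignment end while the read continues to match the germline V 3' tail.
## Returns read_end (0-based half-open end of V attribution on the read),
## germline_end (same, on the gene) and v_deletion.
extend_v_attribution <- function(read, v_gene, v_call) {
  map <- v_call$best$map
  co <- v_call$best$core_offset
  aligned <- !is.na(map$pattern_pos) & !is.na(map$subject_pos)
  g_end <- max(map$pattern_pos[aligned]) + co  # 1-based last aligned germline nt
  r_end <- max(map$subject_pos[aligned])
  glen <- nchar(v_gene$nt_sequence)
  rlen <- nchar(read)
  while (g_end < glen && r_end < rlen &&
         substr(v_gene$nt_sequence, g_end + 1L, g_end + 1L) ==
         substr(read, r_end + 1L, r_end + 1L)) {
    g_end <- g_end + 1L; r_end <- r_end + 1L
  }
  list(read_end = r_end, germline_end = g_end,
       v_deletion = glen - g_end)
}

## maximal templated J attribution: walk leftward from the J alignment start
## while the read continues to match the germline J 5' head; never crosses
## floor_read_pos (V takes precedence over J for shared bases).
extend_j_attribution <- function(read, j_gene, j_call,
                                 floor_read_pos = 0L) {
  map <- j_call$best$map
  aligned <- !is.na(map$pattern_pos) & !is.na(map$subject_pos)
  g_start <- min(map$pattern_pos[aligned])  # 1-based first aligned germline nt
  r_start <- min(map$subject_pos[aligned])
  while (g_start > 1L && r_start > floor_read_pos + 1L &&
         substr(j_gene$nt_sequence, g_start - 1L, g_start - 1L) ==
         substr(read, r_start - 1L, r_start - 1L)) {
    g_start <- g_start - 1L; r_start <- r_start - 1L
  }
  ## the local alignment may itself reach left of the V attribution end;
  ## those shared bases belong to V (V precedence), so retract J
  while (r_start - 1L < floor_read_pos) {
    g_start <- g_start + 1L; r_start <- r_start + 1L
  }
  list(read_start = r_start - 1L,  # 0-based start of J attribution on read
       germline_start = g_start - 1L,
       j_deletion = g_start - 1L)
}
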