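#' Read sequences from FASTA or FASTQ
#'
#' The format is sniffed from the first record character; gzip is handled
#' transparently. Sequences are upper-cased and RNA `U` is normalized to
#' `T`; FASTQ qualities are attached as plain strings.
#'
#' @param path input file.
#' @return data.frame with columns `read_id`, `sequence` and (FASTQ)
#'   `quality`.
#' @export
read_sequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty sequence file: ", path)
  if (startsWith(first, ">")) {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
    sq <- normalize_dna(as.character(seqs))
    assert_dna(sq, "read", iupac = TRUE)
    out <- data.frame(read_id = ids, sequence = sq, stringsAsFactors = FALSE)
  } else if (startsWith(first, "@")) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("truncated FASTQ: record %d is incomplete (%s)",
                   length(lines) %/% 4L + 1L,
                   sub("^@", "", lines[(length(lines) %/% 4L) * 4L + 1L])))
    }
    seqs <- Biostrings::readBStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
    sq <- normalize_dna(as.character(seqs))
    assert_dna(sq, "read", iupac = TRUE)
    out <- data.frame(read_id = ids, sequence = sq,
                      quality = as.character(S4Vectors::mcols(seqs)$qualities),
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognized sequence format (expected FASTA '>' or FASTQ '@'): ", path)
  }
  if (anyDuplicated(out$read_id)) {
    stop("duplicate read id(s): ",
         paste(unique(out$read_id[duplicated(out$read_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Annotate reads against a germline set
#'
#' Runs, per read: V assignment over FR1-FR3, J assignment downstream of
#' the V, D search inside the junction (heavy chains), CDR3 anchoring and
#' junction decomposition. Reads whose V or J cannot be assigned are kept
#' as flagged records with empty calls.
#'
#' @param reads named character vector (or [read_sequences()] data.frame).
#' @param germline_set a `GermlineSet`.
#' @param functional_only restrict V candidates to functional genes
#'   (default TRUE, matching repertoire grouping on potentially functional
#'   germline genes).
#' @param tie_margin,min_v_score,min_j_score,min_d_match,max_p_len see the
#'   stage functions.
#' @param ultralong_aa_threshold CDR3 amino-acid length at or above which
#'   a record is flagged ultra-long (default 40).
#' @return list of `RearrangementRecord`s.
#' @export
annotate_reads <- function(reads, germline_set, functional_only = TRUE,
                           tie_margin = 0, min_v_score = 50, min_j_score = 15,
                           min_d_match = 5L, max_p_len = 4L,
                           ultralong_aa_threshold = 40L) {
  if (is.data.frame(reads)) reads <- stats::setNames(reads$sequence, reads$read_id)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  lapply(seq_along(reads), function(i) {
    annotate_read(ids[i], reads[[i]], germline_set, functional_only,
                  tie_margin, min_v_score, min_j_score, min_d_match,
                  max_p_len, ultralong_aa_threshold)
  })
}

annotate_read <- function(read_id, sequence, germline_set, functional_only,
                          tie_margin, min_v_score, min_j_score, min_d_match,
                          max_p_len, ultralong_aa_threshold) {
  sequence <- normalize_dna(sequence)
  v_call <- assign_v(sequence, germline_set, tie_margin = tie_margin,
                     min_score = min_v_score, functional_only = functional_only)
  j_call <- if (!is.null(v_call)) {
    assign_j(sequence, germline_set, v_call, tie_margin = tie_margin,
             min_score = min_j_score)
  } else NULL
  cdr3 <- NULL; dec <- NULL; d_call <- NULL
  if (!is.null(v_call) && !is.null(j_call)) {
    cdr3 <- locate_cdr3(sequence, v_call, j_call, germline_set)
    dec <- decompose_junction(sequence, germline_set, v_call, j_call,
                              max_p_len = max_p_len, min_d_match = min_d_match)
    if (!is.na(dec$d_gene)) {
      d_call <- new_segment_call(structure(list(
        gene_id = dec$d_gene,
        read_interval = NULL, germline_interval = NULL,
        score = nchar(dec$retained_d), percent_identity = 1,
        mutated_positions = NULL, map = NULL, core_offset = 0L),
        class = "SegmentAlignment"), dec$d_gene)
    }
  }
  productive <- !is.null(cdr3) && cdr3$in_frame &&
    !is.na(cdr3$aa_sequence) && !grepl("*", cdr3$aa_sequence, fixed = TRUE)
  ultralong <- !is.null(cdr3) && cdr3$in_frame && !is.na(cdr3$aa_sequence) &&
    nchar(cdr3$aa_sequence) >= ultralong_aa_threshold
  structure(list(
    read_id = read_id, sequence = sequence,
    v_call = v_call, d_call = d_call, j_call = j_call,
    cdr3 = cdr3, junction_decomposition = dec,
    cdr3_missing = is.null(cdr3),
    unassigned = is.null(v_call) || is.null(j_call),
    productive = productive, ultralong = ultralong,
    shm_count = if (!is.null(v_call)) nrow(v_call$best$mutated_positions) else NA_integer_),
    class = "RearrangementRecord")
}

#' Export annotated records as an AIRR Rearrangement TSV
#'
#' Tab-separated with the AIRR required columns (sequence_id, sequence,
#' rev_comp, productive, v_call, d_call, j_call, sequence_alignment,
#' germline_alignment, junction, junction_aa, v_cigar, d_cigar, j_cigar)
#' plus extension columns for the CDR3, P/N segments, trims, identity and
#' flags. Missing values are empty strings; booleans are `T`/`F`.
#'
#' @param records list of records from [annotate_reads()].
#' @param path output file.
#' @param germline_set the germline set used (for alignment strings).
#' @return the data.frame written, invisibly.
#' @export
write_airr <- function(records, path, germline_set = NULL) {
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  bool <- function(x) ifelse(is.na(x), "", ifelse(x, "T", "F"))
  rows <- lapply(records, function(r) {
    v <- r$v_call; j <- r$j_call; d <- r$d_call
    dec <- r$junction_decomposition; c3 <- r$cdr3
    junction <- junction_aa <- ""
    if (!is.null(c3)) {
      junction <- substr(r$sequence, c3$anchor_c_position + 1L,
                         c3$anchor_wf_position + 3L)
      if (nchar(junction) %% 3L == 0L) junction_aa <- translate_frame(junction, 0L)
    }
    seq_aln <- germ_aln <- ""
    if (!is.null(v) && !is.null(v$best$map)) {
      seq_aln <- paste(v$best$map$subject_base, collapse = "")
      germ_aln <- paste(v$best$map$pattern_base, collapse = "")
    }
    data.frame(
      sequence_id = r$read_id, sequence = r$sequence, rev_comp = "F",
      productive = bool(r$productive),
      v_call = if (!is.null(v)) v$best$gene_id else "",
      d_call = if (!is.null(d)) d$best$gene_id else "",
      j_call = if (!is.null(j)) j$best$gene_id else "",
      sequence_alignment = seq_aln, germline_alignment = germ_aln,
      junction = junction, junction_aa = junction_aa,
      v_cigar = if (!is.null(v)) map_cigar(v$best$map) else "",
      d_cigar = "", j_cigar = if (!is.null(j)) map_cigar(j$best$map) else "",
      cdr3 = if (!is.null(c3)) c3$nt_sequence else "",
      cdr3_aa = if (!is.null(c3)) blank(c3$aa_sequence) else "",
      v_call_ties = if (!is.null(v)) paste(v$ties, collapse = ",") else "",
      p1 = if (!is.null(dec)) dec$p1 else "",
      p2 = if (!is.null(dec)) dec$p2 else "",
      n1 = if (!is.null(dec)) dec$n1 else "",
      n2 = if (!is.null(dec)) dec$n2 else "",
      v_deletion = if (!is.null(dec)) blank(dec$v_deletion) else "",
      j_deletion = if (!is.null(dec)) blank(dec$j_deletion) else "",
      d_deletion_5p = if (!is.null(dec)) blank(dec$d_deletion_5p) else "",
      d_deletion_3p = if (!is.null(dec)) blank(dec$d_deletion_3p) else "",
      v_identity = if (!is.null(v)) sprintf("%.6f", v$best$percent_identity) else "",
      shm_count = blank(r$shm_count),
      ultralong = bool(r$ultralong),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    cols <- c("sequence_id", "sequence", "rev_comp", "productive", "v_call",
              "d_call", "j_call", "sequence_alignment", "germline_alignment",
              "junction", "junction_aa", "v_cigar", "d_cigar", "j_cigar",
              "cdr3", "cdr3_aa", "v_call_ties", "p1", "p2", "n1", "n2",
              "v_deletion", "j_deletion", "d_deletion_5p", "d_deletion_3p",
              "v_identity", "shm_count", "ultralong")
    tab <- as.data.frame(stats::setNames(rep(list(character(0L)),
                                             length(cols)), cols))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(tab)
}

## CIGAR string of an alignment map (M/I/D runs; I = extra read base,
## D = germline base missing from the read)
map_cigar <- function(map) {
  if (is.null(map)) return("")
  op <- ifelse(!is.na(map$pattern_pos) & !is.na(map$subject_pos), "M",
               ifelse(is.na(map$pattern_pos), "I", "D"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Read back an AIRR Rearrangement TSV
#'
#' @param path the TSV file.
#' @return data.frame with character columns as written by [write_airr()].
#' @export
read_airr <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Run the full annotation pipeline on a read set
#'
#' Stages: primer/length QC, V(D)J assignment, CDR3/junction decomposition,
#' SHM analytics and usage statistics. Each stage's tables are written
#' under `out_dir`; a rerun with identical inputs is bit-identical (no
#' timestamps in outputs). Configuration defaults mirror the stage
#' functions; unknown configuration keys are rejected.
#'
#' @param reads named character vector, data.frame, or path to FASTA/FASTQ.
#' @param germline_set a `GermlineSet` (or path to a germline FASTA, with
#'   `regions_path` in `config`).
#' @param out_dir output directory (created).
#' @param config named list of overrides: `forward_primer`,
#'   `reverse_primer`, `min_length`, `max_primer_mm`, `functional_only`,
#'   `tie_margin`, `min_v_score`, `min_j_score`, `min_d_match`,
#'   `max_p_len`, `hotspot_motifs`, `regions_path`, `skip_qc`.
#' @return invisible list with the per-stage objects and output paths.
#' @export
run_pipeline <- function(reads, germline_set, out_dir, config = list()) {
  defaults <- list(
    forward_primer = "AAGCAGTGGTATCAACGCAGAGT",
    reverse_primer = NULL, min_length = 400L, max_primer_mm = 2L,
    functional_only = TRUE, tie_margin = 0, min_v_score = 50,
    min_j_score = 15, min_d_match = 5L, max_p_len = 4L,
    hotspot_motifs = c("WRCY", "RGYW"), regions_path = NULL,
    skip_qc = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.character(germline_set) && length(germline_set) == 1L) {
    germline_set <- classify_germline_set(
      load_germline(germline_set, cfg$regions_path))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_sequences(reads)
  }
  if (is.data.frame(reads)) reads <- stats::setNames(reads$sequence, reads$read_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  if (is.null(cfg$reverse_primer)) {
    cfg$reverse_primer <- decoration_for(germline_set$locus)$reverse_primer
  }
  if (cfg$skip_qc) {
    kept <- reads
    qc <- NULL
  } else {
    qcres <- filter_reads(reads, cfg$forward_primer, cfg$reverse_primer,
                          min_length = cfg$min_length,
                          max_primer_mm = cfg$max_primer_mm)
    kept <- qcres$kept
    qc <- qcres$report
    write_qc_report(qc, pth("qc_report.tsv"))
  }

  records <- annotate_reads(kept, germline_set,
                            functional_only = cfg$functional_only,
                            tie_margin = cfg$tie_margin,
                            min_v_score = cfg$min_v_score,
                            min_j_score = cfg$min_j_score,
                            min_d_match = cfg$min_d_match,
                            max_p_len = cfg$max_p_len)
  airr <- write_airr(records, pth("rearrangements.tsv"), germline_set)

  jstats <- junction_length_stats(records)
  utils::write.table(jstats$summary, pth("junction_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (q in names(jstats$tables)) {
    utils::write.table(jstats$tables[[q]], pth(sprintf("hist_%s.tsv", q)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  shm <- shm_frequency(records)
  spectrum <- substitution_spectrum(records)
  profiles <- per_site_profile(records, germline_set)
  hotspots <- hotspot_analysis(records, germline_set, cfg$hotspot_motifs)
  utils::write.table(shm$per_gene, pth("shm_per_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("overall_shm_pct\t%.6f", shm$overall_pct),
             pth("shm_overall.tsv"))
  utils::write.table(spectrum, pth("substitution_spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof_tab <- do.call(rbind, lapply(names(profiles), function(g)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), profiles[[g]])))
  utils::write.table(prof_tab, pth("per_site_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hot_tab <- do.call(rbind, lapply(hotspots, function(h)
    data.frame(motif = h$motif, mutable_base = h$mutable_base,
               n_hotspot_positions = h$n_hotspot_positions,
               hotspot_frequency = h$hotspot$frequency,
               baseline_frequency = h$baseline$frequency,
               enrichment = h$enrichment, stringsAsFactors = FALSE)))
  utils::write.table(hot_tab, pth("hotspots.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  usage <- list(
    v_gene = usage_frequencies(records, "V", "gene"),
    v_clan = usage_frequencies(records, "V", "clan", germline_set),
    j_gene = usage_frequencies(records, "J", "gene"))
  if (germline_set$locus == "IGH") {
    usage$d_gene <- usage_frequencies(records, "D", "gene")
  }
  for (u in names(usage)) {
    utils::write.table(usage[[u]], pth(sprintf("usage_%s.tsv", u)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  comb <- combination_table(records, "clan", germline_set)
  utils::write.table(comb, pth("combinations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  contrib <- segment_contribution_stats(records)
  utils::write.table(contrib, pth("segment_contributions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  resolved <- cfg
  resolved$locus <- germline_set$locus
  yaml::write_yaml(resolved[order(names(resolved))], pth("config.yaml"))

  invisible(list(qc = qc, records = records, airr = airr,
                 junction_stats = jstats, shm = shm, spectrum = spectrum,
                 profiles = profiles, hotspots = hotspots, usage = usage,
                 combinations = comb, contributions = contrib,
                 out_dir = out_dir))
}
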