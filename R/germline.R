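#' Construct a germline gene segment
#'
#' A `GermlineGene` holds one germline V, D, J or C segment: its nucleotide
#' sequence, locus, optional region boundaries (for V genes: FR1, CDR1, FR2,
#' CDR2, FR3 and optionally a leader), a functionality class and an optional
#' clan label and attached RSS.
#'
#' Coordinates are 0-based half-open throughout.
#'
#' @param gene_id unique identifier.
#' @param locus one of `"IGH"`, `"IGK"`, `"IGL"`.
#' @param segment_type one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param nt_sequence DNA string (A/C/G/T/N).
#' @param region_bounds named list of `c(start, end)` integer pairs
#'   (0-based half-open) with names among `leader`, `FR1`, `CDR1`, `FR2`,
#'   `CDR2`, `FR3`. V genes only; D genes must not carry bounds.
#' @param functionality `"functional"`, `"ORF"`, `"pseudogene"`,
#'   `"incomplete"` or `NA` (not yet classified).
#' @param clan optional clan label.
#' @param rss optional `Rss` object (see [find_rss()]).
#' @return an object of class `GermlineGene`.
#' @export
germline_gene <- function(gene_id, locus, segment_type, nt_sequence,
                          region_bounds = NULL, functionality = NA_character_,
                          clan = NA_character_, rss = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  locus <- match.arg(locus, c("IGH", "IGK", "IGL"))
  segment_type <- match.arg(segment_type, c("V", "D", "J", "C"))
  nt_sequence <- normalize_dna(nt_sequence)
  assert_dna(nt_sequence, sprintf("gene '%s'", gene_id))
  if (segment_type == "D" && !is.null(region_bounds)) {
    stop(sprintf("D gene '%s' must not carry region_bounds", gene_id))
  }
  if (!is.null(region_bounds)) {
    region_bounds <- validate_region_bounds(region_bounds, nchar(nt_sequence), gene_id)
  }
  structure(list(gene_id = gene_id, locus = locus,
                 segment_type = segment_type, nt_sequence = nt_sequence,
                 region_bounds = region_bounds, functionality = functionality,
                 clan = clan, rss = rss),
            class = "GermlineGene")
}

REGION_ORDER <- c("leader", "FR1", "CDR1", "FR2", "CDR2", "FR3")

validate_region_bounds <- function(bounds, seq_len, gene_id) {
  nm <- names(bounds)
  if (is.null(nm) || !all(nm %in% REGION_ORDER)) {
    stop(sprintf("gene '%s': region names must be among %s", gene_id,
                 paste(REGION_ORDER, collapse = ", ")))
  }
  bounds <- bounds[order(match(nm, REGION_ORDER))]
  prev_end <- -1L
  for (r in names(bounds)) {
    b <- as.integer(bounds[[r]])
    if (length(b) != 2L || b[1] < 0L || b[2] > seq_len || b[1] >= b[2]) {
      stop(sprintf("gene '%s': invalid bounds for %s", gene_id, r))
    }
    if (b[1] < prev_end) {
      stop(sprintf("gene '%s': region %s overlaps or is out of order", gene_id, r))
    }
    prev_end <- b[2]
    bounds[[r]] <- b
  }
  bounds
}

#' @export
print.GermlineGene <- function(x, ...) {
  cat(sprintf("GermlineGene %s [%s %s] %d nt, functionality=%s, clan=%s\n",
              x$gene_id, x$locus, x$segment_type, nchar(x$nt_sequence),
              x$functionality, x$clan))
  invisible(x)
}

## region sub-sequence (0-based half-open bounds -> 1-based substr)
region_seq <- function(gene, region) {
  b <- gene$region_bounds[[region]]
  if (is.null(b)) return(NULL)
  substr(gene$nt_sequence, b[1] + 1L, b[2])
}

## FR1..FR3 core of a V gene (the alignment/SHM region)
v_core_seq <- function(gene) {
  b1 <- gene$region_bounds[["FR1"]]; b3 <- gene$region_bounds[["FR3"]]
  if (is.null(b1) || is.null(b3)) return(NULL)
  substr(gene$nt_sequence, b1[1] + 1L, b3[2])
}

## junction-forming 3' end of a V gene (everything after FR3)
v_tail_seq <- function(gene) {
  b3 <- gene$region_bounds[["FR3"]]
  if (is.null(b3)) return(NULL)
  substr(gene$nt_sequence, b3[2] + 1L, nchar(gene$nt_sequence))
}

#' Build a germline set
#'
#' @param genes list of [germline_gene()] objects (ids must be unique).
#' @param locus locus label.
#' @param metadata optional named list (source, version, ...).
#' @return object of class `GermlineSet`; `$genes` is keyed by gene_id.
#' @export
germline_set <- function(genes, locus = NULL, metadata = list()) {
  stopifnot(is.list(genes), length(genes) >= 1L)
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  if (is.null(locus)) locus <- genes[[1L]]$locus
  names(genes) <- ids
  structure(list(genes = genes, locus = locus, metadata = metadata),
            class = "GermlineSet")
}

#' @export
print.GermlineSet <- function(x, ...) {
  tp <- vapply(x$genes, function(g) g$segment_type, character(1L))
  cat(sprintf("GermlineSet [%s]: %s\n", x$locus,
              paste(sprintf("%d %s", as.integer(table(tp)[c("V","D","J","C")]),
                            c("V","D","J","C"))[!is.na(table(tp)[c("V","D","J","C")])],
                    collapse = ", ")))
  invisible(x)
}

## subset by segment type, returning the gene list (keyed)
genes_of_type <- function(set, type) {
  Filter(function(g) g$segment_type == type, set$genes)
}

#' Load a germline set from FASTA (plus an optional region table)
#'
#' FASTA headers are parsed as `gene_id [locus] [segment_type]`
#' (whitespace-separated; locus/type may instead be supplied through the
#' region table or inferred from the id prefix, e.g. `IGHV1`).
#' The region table is tab-separated with columns
#' `gene_id, region, start, end` (0-based half-open).
#'
#' @param path FASTA file.
#' @param regions_path optional region table path.
#' @param locus fallback locus when not encoded in the records.
#' @return a `GermlineSet`.
#' @export
load_germline <- function(path, regions_path = NULL, locus = "IGH") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in germline FASTA")
  hdr <- strsplit(names(seqs), "\\s+")
  ids <- vapply(hdr, `[[`, character(1L), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate gene id(s) in FASTA: %s",
                                paste(unique(dup), collapse = ", ")))
  regions <- NULL
  if (!is.null(regions_path)) {
    regions <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "region", "start", "end")
    if (!all(need %in% names(regions))) {
      stop("region table must have columns gene_id, region, start, end")
    }
    unknown <- setdiff(unique(regions$gene_id), ids)
    if (length(unknown)) {
      stop(sprintf("region table references unknown gene id(s): %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  genes <- lapply(seq_along(seqs), function(i) {
    id <- ids[i]
    extra <- hdr[[i]][-1L]
    loc <- extra[extra %in% c("IGH", "IGK", "IGL")][1L]
    if (is.na(loc)) {
      loc <- c(IGH = "IGH", IGK = "IGK", IGL = "IGL")[substr(id, 1L, 3L)]
      if (is.na(loc)) loc <- locus
    }
    st <- extra[extra %in% c("V", "D", "J", "C")][1L]
    if (is.na(st)) {
      st <- substr(sub("^IG[HKL]", "", id), 1L, 1L)
      if (!st %in% c("V", "D", "J", "C")) {
        stop(sprintf("cannot determine segment type for record '%s'", id))
      }
    }
    bounds <- NULL
    if (!is.null(regions)) {
      rr <- regions[regions$gene_id == id, , drop = FALSE]
      if (nrow(rr)) {
        bounds <- lapply(seq_len(nrow(rr)),
                         function(k) c(rr$start[k], rr$end[k]))
        names(bounds) <- rr$region
      }
    }
    germline_gene(id, loc, st, as.character(seqs[[i]]), region_bounds = bounds)
  })
  loci <- unique(vapply(genes, function(g) g$locus, character(1L)))
  germline_set(genes, locus = if (length(loci) == 1L) loci else locus,
               metadata = list(source = path))
}

#' Write a germline set to FASTA
#'
#' @param set a `GermlineSet`.
#' @param path output file.
#' @param regions_path optional path for the region table.
#' @return `path`, invisibly.
#' @export
write_germline <- function(set, path, regions_path = NULL) {
  lines <- unlist(lapply(set$genes, function(g) {
    c(sprintf(">%s %s %s", g$gene_id, g$locus, g$segment_type), g$nt_sequence)
  }), use.names = FALSE)
  writeLines(lines, path)
  if (!is.null(regions_path)) {
    rows <- do.call(rbind, lapply(set$genes, function(g) {
      if (is.null(g$region_bounds)) return(NULL)
      data.frame(gene_id = g$gene_id, region = names(g$region_bounds),
                 start = vapply(g$region_bounds, `[`, integer(1L), 1L),
                 end = vapply(g$region_bounds, `[`, integer(1L), 2L),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, regions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Classify every gene of a germline set and assign V clans
#'
#' Runs [classify_v_gene()], [classify_j_gene()] and [d_open_frames()] over
#' the set, stores the resulting functionality labels, and labels the
#' functional V genes with [assign_clans()] clans.
#'
#' @param set a `GermlineSet`.
#' @param identity_threshold clan identity threshold (default 0.75).
#' @return the set with `functionality` and `clan` filled in.
#' @export
classify_germline_set <- function(set, identity_threshold = 0.75) {
  stopifnot(inherits(set, "GermlineSet"))
  for (id in names(set$genes)) {
    g <- set$genes[[id]]
    set$genes[[id]]$functionality <- switch(
      g$segment_type,
      V = classify_v_gene(g)$functionality,
      J = classify_j_gene(g)$functionality,
      D = if (length(d_open_frames(g))) "functional" else "pseudogene",
      "functional")
  }
  func <- Filter(function(g) g$functionality == "functional",
                 genes_of_type(set, "V"))
  if (length(func)) {
    cl <- assign_clans(func, identity_threshold)$clans
    for (id in names(cl)) set$genes[[id]]$clan <- cl[[id]]
  }
  set
}

#' Classify a germline V gene (IMGT-style functionality)
#'
#' A V gene is `functional` when its FR1-FR3 reading frame is open (no stop,
#' regions in frame), both conserved cysteines (the first-Cys in FR1 and the
#' second-Cys terminating FR3) are present, the leader (if annotated) starts
#' with ATG, and a downstream RSS is attached when genomic context is
#' provided. An intact frame violating a conserved-residue or regulatory
#' criterion is `ORF`; an internal stop or frameshift is `pseudogene`; a
#' truncated or unalignable gene is `incomplete`.
#'
#' Conserved-Cys positions are taken from the gene's region annotation: the
#' first-Cys is amino acid 23 counting from the FR1 start (falling back to
#' the last Cys codon of FR1 when FR1 is shorter than 23 codons) and the
#' second-Cys is the last codon of FR3. With `template` given, positions are
#' instead projected from the template gene through a pairwise alignment, so
#' indels relative to the numbering template do not shift them.
#'
#' @param gene a V `GermlineGene`.
#' @param template optional numbering-template `GermlineGene` whose Cys
#'   positions are projected onto `gene`.
#' @param require_rss require an attached RSS for the `functional` label
#'   (use when the gene came with genomic context). Default `FALSE`.
#' @return list with `functionality` and `reason`.
#' @export
classify_v_gene <- function(gene, template = NULL, require_rss = FALSE) {
  stopifnot(inherits(gene, "GermlineGene"), gene$segment_type == "V")
  b <- gene$region_bounds
  if (is.null(b) || is.null(b$FR1) || is.null(b$FR3)) {
    return(list(functionality = "incomplete", reason = "unalignable"))
  }
  if (b$FR3[2] > nchar(gene$nt_sequence)) {
    return(list(functionality = "incomplete", reason = "truncated"))
  }
  core <- v_core_seq(gene)
  ## frameshift: FR/CDR spans must keep FR1..FR3 in one frame
  for (r in intersect(c("FR1", "CDR1", "FR2", "CDR2", "FR3"), names(b))) {
    if ((b[[r]][2] - b[[r]][1]) %% 3L != 0L) {
      return(list(functionality = "pseudogene",
                  reason = sprintf("frameshift in %s", r)))
    }
  }
  aa <- translate_frame(core, 0L)
  if (grepl("*", aa, fixed = TRUE)) {
    return(list(functionality = "pseudogene", reason = "internal stop codon"))
  }
  cys <- conserved_cys_positions(gene, template)
  aa_chars <- chars(aa)
  c1 <- !is.na(cys[1]) && cys[1] <= length(aa_chars) && aa_chars[cys[1]] == "C"
  c2 <- !is.na(cys[2]) && cys[2] <= length(aa_chars) && aa_chars[cys[2]] == "C"
  if (!c2) return(list(functionality = "ORF", reason = "second-Cys (FR3 104) not conserved"))
  if (!c1) return(list(functionality = "ORF", reason = "first-Cys (FR1 23) not conserved"))
  if (!is.null(b$leader)) {
    lead <- region_seq(gene, "leader")
    if (substr(lead, 1L, 3L) != "ATG") {
      return(list(functionality = "ORF", reason = "no translation initiation codon"))
    }
  }
  if (require_rss && is.null(gene$rss)) {
    return(list(functionality = "ORF", reason = "no downstream RSS"))
  }
  list(functionality = "functional", reason = "all criteria met")
}

## amino-acid indices (1-based, relative to the FR1-start frame) of the two
## conserved Cys. Optionally projected from a numbering template by alignment.
conserved_cys_positions <- function(gene, template = NULL) {
  if (!is.null(template)) {
    tpos <- conserved_cys_positions(template, NULL)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(v_core_seq(template)),
      Biostrings::DNAString(v_core_seq(gene)),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 4, gapExtension = 1)
    map <- alignment_map(aln)
    proj <- function(aa_i) {
      nt <- (aa_i - 1L) * 3L + 1L          # first nt of the codon in template core
      hit <- map$subject_pos[match(nt, map$pattern_pos)]
      if (is.na(hit)) return(NA_integer_)
      as.integer((hit - 1L) %/% 3L + 1L)
    }
    return(c(proj(tpos[1]), proj(tpos[2])))
  }
  b <- gene$region_bounds
  fr1_aa <- (b$FR1[2] - b$FR1[1]) %/% 3L
  c1 <- if (fr1_aa >= 23L) 23L else {
    fr1_aa_seq <- chars(translate_frame(region_seq(gene, "FR1"), 0L))
    w <- which(fr1_aa_seq == "C")
    if (length(w)) w[length(w)] else NA_integer_
  }
  core_aa <- (b$FR3[2] - b$FR1[1]) %/% 3L   # last FR3 codon index in core frame
  c(c1, core_aa)
}

#' Classify a germline J gene
#'
#' Functional iff some reading frame contains the FR4 motif W-G-X-G (IGH) or
#' F-G-X-G (light chains) with the frame open (no stop) through the motif;
#' otherwise pseudogene. The presence of the downstream `TVSS` motif is
#' returned as an advisory flag only.
#'
#' @param gene a J `GermlineGene`.
#' @param locus locus determining the motif (defaults to the gene's locus).
#' @return list with `functionality`, `frame` (0/1/2 or NA), `motif_aa_start`
#'   (1-based AA index, NA if absent) and `tvss` flag.
#' @export
classify_j_gene <- function(gene, locus = gene$locus) {
  stopifnot(inherits(gene, "GermlineGene"), gene$segment_type == "J")
  key <- paste(locus, gene$nt_sequence)
  hit <- .igj_germ_cache$j[[key]]
  if (!is.null(hit)) return(hit)
  first <- if (locus == "IGH") "W" else "F"
  rx <- paste0(first, "G.G")
  res <- NULL
  for (f in 0:2) {
    aa <- translate_frame(gene$nt_sequence, f)
    m <- regexpr(rx, aa)
    if (m > 0L) {
      before <- substr(aa, 1L, as.integer(m) + 3L)
      if (!grepl("*", before, fixed = TRUE)) {
        tvss <- grepl("TVSS", aa, fixed = TRUE)
        res <- list(functionality = "functional", frame = f,
                    motif_aa_start = as.integer(m), tvss = tvss)
        break
      }
    }
  }
  if (is.null(res)) {
    res <- list(functionality = "pseudogene", frame = NA_integer_,
                motif_aa_start = NA_integer_, tvss = FALSE)
  }
  .igj_germ_cache$j[[key]] <- res
  res
}

.igj_germ_cache <- new.env(parent = emptyenv())
.igj_germ_cache$j <- list()

#' Reading frames of a D gene with no stop codon
#'
#' @param gene a D `GermlineGene`.
#' @return integer vector, subset of `c(0, 1, 2)`.
#' @export
d_open_frames <- function(gene) {
  stopifnot(inherits(gene, "GermlineGene"), gene$segment_type == "D")
  frames <- integer(0L)
  for (f in 0:2) {
    aa <- translate_frame(gene$nt_sequence, f)
    if (!grepl("*", aa, fixed = TRUE)) frames <- c(frames, f)
  }
  frames
}

#' Cluster V genes into clans by FR1-FR3 nucleotide identity
#'
#' Single-linkage clustering: two genes share a clan when a chain of pairwise
#' identities at or above `identity_threshold` connects them. Clans are
#' labelled with roman numerals in descending clan size; ties are broken by
#' the lexicographically smallest member id, making the labelling canonical
#' (input-order invariant).
#'
#' @param genes list of V `GermlineGene` with FR1-FR3 bounds.
#' @param identity_threshold pairwise identity threshold (default 0.75).
#' @return list with `clans` (named character vector gene_id -> label) and
#'   `excluded` (ids lacking FR1-FR3 bounds).
#' @export
assign_clans <- function(genes, identity_threshold = 0.75) {
  if (inherits(genes, "GermlineSet")) genes <- genes_of_type(genes, "V")
  cores <- lapply(genes, v_core_seq)
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  has <- !vapply(cores, is.null, logical(1L))
  excluded <- ids[!has]
  ids <- ids[has]; cores <- cores[has]
  n <- length(ids)
  if (n == 0L) return(list(clans = stats::setNames(character(0L), character(0L)),
                           excluded = excluded))
  ## order by id so the union-find result is input-order invariant
  o <- order(ids)
  ids <- ids[o]; cores <- cores[o]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (pairwise_identity(cores[[i]], cores[[j]]) >= identity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  groups <- split(ids, comp)
  sizes <- vapply(groups, length, integer(1L))
  firsts <- vapply(groups, function(g) sort(g)[1L], character(1L))
  ord <- order(-sizes, firsts)
  labels <- as.character(utils::as.roman(seq_along(groups)))
  out <- character(n); names(out) <- ids
  for (k in seq_along(ord)) out[groups[[ord[k]]]] <- labels[k]
  list(clans = out, excluded = excluded)
}

#' Pairwise nucleotide identity of two sequences
#'
#' Global alignment identity: matches / alignment length.
#'
#' @param a,b DNA strings.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 4, gapExtension = 1)
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))
  sum(p == s & p != "-") / length(p)
}
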