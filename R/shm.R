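#' Somatic hypermutation frequency
#'
#' SHM frequency = observed mutant bases / total sequenced (aligned,
#' non-gap) bases over FR1-FR3, reported as a percentage, overall and per
#' germline V group. Records with ambiguous (tied) V calls are excluded by
#' default because their mutation sets depend on which tied gene is chosen.
#'
#' @param records list of annotated records (see [annotate_reads()]).
#' @param include_ambiguous include tied V calls using the best hit
#'   (default FALSE).
#' @return list with `overall_pct` (percentage, NA with a warning when no
#'   bases are covered), `per_gene` data.frame (gene, mutated, covered,
#'   pct) and the raw totals.
#' @export
shm_frequency <- function(records, include_ambiguous = FALSE) {
  records <- shm_eligible(records, include_ambiguous)
  per <- lapply(records, function(r) {
    map <- r$v_call$best$map
    aligned <- !is.na(map$pattern_pos) & !is.na(map$subject_pos) &
      map$subject_base != "N"
    data.frame(gene = r$v_call$best$gene_id,
               mutated = sum(aligned & map$pattern_base != map$subject_base),
               covered = sum(aligned), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  if (is.null(tab) || sum(tab$covered) == 0L) {
    warning("no covered bases; SHM frequency undefined")
    return(list(overall_pct = NA_real_,
                per_gene = data.frame(gene = character(0L), mutated = integer(0L),
                                      covered = integer(0L), pct = numeric(0L)),
                mutated = 0L, covered = 0L))
  }
  agg <- stats::aggregate(cbind(mutated, covered) ~ gene, tab, sum)
  agg$pct <- 100 * agg$mutated / agg$covered
  list(overall_pct = 100 * sum(tab$mutated) / sum(tab$covered),
       per_gene = agg, mutated = sum(tab$mutated), covered = sum(tab$covered))
}

shm_eligible <- function(records, include_ambiguous) {
  records <- Filter(function(r) !is.null(r$v_call), records)
  if (!include_ambiguous) {
    records <- Filter(function(r) !r$v_call$ambiguous, records)
  }
  records
}

#' Per-site mutation profile over a germline V
#'
#' For each germline FR1-FR3 position: how many reads cover it, how many
#' carry a substitution there, and the resulting frequency. Positions
#' opposite read gaps or N bases contribute to neither count.
#'
#' @param records annotated records, all assigned (or restricted) to one or
#'   more germline V genes; profiles are computed per gene.
#' @param germline_set the `GermlineSet` (for region labels).
#' @param include_ambiguous see [shm_frequency()].
#' @return named list (by gene) of data.frames with columns
#'   `germline_position` (0-based), `region`, `coverage`, `mutations`,
#'   `frequency`.
#' @export
per_site_profile <- function(records, germline_set, include_ambiguous = FALSE) {
  records <- shm_eligible(records, include_ambiguous)
  by_gene <- split(records, vapply(records, function(r)
    r$v_call$best$gene_id, character(1L)))
  lapply(by_gene, function(rs) {
    gene <- germline_set$genes[[rs[[1L]]$v_call$best$gene_id]]
    b <- gene$region_bounds
    pos0 <- b$FR1[1]; pos1 <- b$FR3[2]
    positions <- pos0:(pos1 - 1L)
    cov <- integer(length(positions)); mut <- integer(length(positions))
    for (r in rs) {
      map <- r$v_call$best$map
      co <- r$v_call$best$core_offset
      ok <- !is.na(map$pattern_pos) & !is.na(map$subject_pos) &
        map$subject_base != "N"
      gp <- map$pattern_pos[ok] - 1L + co
      idx <- gp - pos0 + 1L
      keep <- idx >= 1L & idx <= length(positions)
      cov[idx[keep]] <- cov[idx[keep]] + 1L
      mm <- map$pattern_base[ok] != map$subject_base[ok]
      mi <- idx[keep & mm]
      mut[mi] <- mut[mi] + 1L
    }
    region <- region_label(gene, positions)
    data.frame(germline_position = positions, region = region,
               coverage = cov, mutations = mut,
               frequency = ifelse(cov > 0L, mut / cov, NA_real_),
               stringsAsFactors = FALSE)
  })
}

region_label <- function(gene, positions) {
  lab <- rep(NA_character_, length(positions))
  for (r in names(gene$region_bounds)) {
    b <- gene$region_bounds[[r]]
    lab[positions >= b[1] & positions < b[2]] <- r
  }
  lab
}

#' Substitution spectrum of observed mutations
#'
#' Counts of the 12 substitution classes (each of A, T, C, G to the other
#' three bases) with percentages over all observed mutant bases.
#'
#' @param records annotated records.
#' @param include_ambiguous see [shm_frequency()].
#' @return data.frame with `from`, `to`, `count`, `percent` (percent is NA
#'   when there are no mutations).
#' @export
substitution_spectrum <- function(records, include_ambiguous = FALSE) {
  records <- shm_eligible(records, include_ambiguous)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(from = bases, to = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  grid <- grid[order(grid$from, grid$to), , drop = FALSE]
  cnt <- stats::setNames(integer(nrow(grid)), paste(grid$from, grid$to))
  for (r in records) {
    mp <- r$v_call$best$mutated_positions
    if (is.null(mp) || !nrow(mp)) next
    ok <- mp$germline_base %in% bases & mp$read_base %in% bases
    key <- paste(mp$germline_base[ok], mp$read_base[ok])
    tb <- table(key)
    cnt[names(tb)] <- cnt[names(tb)] + as.integer(tb)
  }
  total <- sum(cnt)
  data.frame(from = grid$from, to = grid$to, count = as.integer(cnt),
             percent = if (total > 0L) 100 * cnt / total else rep(NA_real_, nrow(grid)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AID hotspot mutation analysis
#'
#' Scans germline V FR1-FR3 sequences for AID hotspot motifs (IUPAC:
#' W=A/T, R=A/G, Y=C/T, D=A/G/T). The mutable base is the C of `WRCY`/`WRCH`
#' (position 3) and the G of `RGYW`/`DGYW` (position 2). Mutation
#' frequencies at hotspot positions are computed from the per-site profile,
#' broken down by substitution class, against the baseline of all
#' non-hotspot C (respectively G) positions. Enrichment = hotspot
#' frequency / baseline frequency (NA when the baseline is 0).
#'
#' @param records annotated records.
#' @param germline_set the `GermlineSet`.
#' @param motif_set character vector from `WRCY`, `RGYW`, `WRCH`, `DGYW`
#'   (default `c("WRCY", "RGYW")`).
#' @param include_ambiguous see [shm_frequency()].
#' @return named list per motif: `n_hotspot_positions`, `hotspot`
#'   (coverage, mutations, frequency, per-substitution frequencies),
#'   `baseline` (same for non-hotspot C/G), `enrichment`.
#' @export
hotspot_analysis <- function(records, germline_set,
                             motif_set = c("WRCY", "RGYW"),
                             include_ambiguous = FALSE) {
  if (!length(motif_set)) stop("empty motif set")
  bad <- setdiff(motif_set, c("WRCY", "RGYW", "WRCH", "DGYW"))
  if (length(bad)) stop(sprintf("unknown motif(s): %s", paste(bad, collapse = ", ")))
  records <- shm_eligible(records, include_ambiguous)
  profiles <- per_site_profile(records, germline_set,
                               include_ambiguous = include_ambiguous)
  out <- list()
  for (motif in motif_set) {
    target <- if (motif %in% c("WRCY", "WRCH")) "C" else "G"
    hot_cov <- 0L; hot_mut <- 0L; base_cov <- 0L; base_mut <- 0L
    n_hot <- 0L
    sub_counts <- stats::setNames(integer(3L),
                                  setdiff(c("A", "C", "G", "T"), target))
    sub_cov <- 0L
    for (gid in names(profiles)) {
      gene <- germline_set$genes[[gid]]
      core <- v_core_seq(gene)
      co <- gene$region_bounds$FR1[1]
      hits <- hotspot_positions(core, motif)         # 0-based in core
      hot_gp <- hits + co
      prof <- profiles[[gid]]
      cv <- chars(core)
      is_target <- which(cv == target) - 1L + co
      base_gp <- setdiff(is_target, hot_gp)
      hsel <- prof$germline_position %in% hot_gp
      bsel <- prof$germline_position %in% base_gp
      n_hot <- n_hot + length(hot_gp)
      hot_cov <- hot_cov + sum(prof$coverage[hsel])
      hot_mut <- hot_mut + sum(prof$mutations[hsel])
      base_cov <- base_cov + sum(prof$coverage[bsel])
      base_mut <- base_mut + sum(prof$mutations[bsel])
      ## per-substitution classes at hotspot positions
      for (r in Filter(function(r) r$v_call$best$gene_id == gid, records)) {
        mp <- r$v_call$best$mutated_positions
        if (is.null(mp) || !nrow(mp)) next
        sel <- mp$germline_position %in% hot_gp & mp$germline_base == target
        tb <- table(mp$read_base[sel])
        hit_names <- intersect(names(tb), names(sub_counts))
        sub_counts[hit_names] <- sub_counts[hit_names] + as.integer(tb[hit_names])
      }
    }
    sub_freq <- if (hot_cov > 0L) sub_counts / hot_cov else
      stats::setNames(rep(NA_real_, 3L), names(sub_counts))
    hot_freq <- if (hot_cov > 0L) hot_mut / hot_cov else NA_real_
    base_freq <- if (base_cov > 0L) base_mut / base_cov else NA_real_
    enrich <- if (!is.na(base_freq) && base_freq > 0) hot_freq / base_freq else NA_real_
    out[[motif]] <- list(
      motif = motif, mutable_base = target, n_hotspot_positions = n_hot,
      hotspot = list(coverage = hot_cov, mutations = hot_mut,
                     frequency = hot_freq,
                     by_substitution = sub_freq),
      baseline = list(coverage = base_cov, mutations = base_mut,
                      frequency = base_freq),
      enrichment = enrich)
  }
  out
}

#' Hotspot mutable-base positions in a sequence
#'
#' 0-based positions of the mutable C (for `WRCY`/`WRCH`) or G (for
#' `RGYW`/`DGYW`) of every motif occurrence.
#'
#' @param sequence DNA string.
#' @param motif motif name.
#' @return integer vector of 0-based positions.
#' @export
hotspot_positions <- function(sequence, motif) {
  offset <- if (motif %in% c("WRCY", "WRCH")) 2L else 1L
  rx <- iupac_regex(motif)
  hits <- integer(0L)
  from <- 1L
  repeat {
    m <- regexpr(rx, substr(sequence, from, nchar(sequence)))
    if (m < 0L) break
    pos <- from + as.integer(m) - 1L
    hits <- c(hits, pos - 1L + offset)
    from <- pos + 1L   # overlapping occurrences allowed
  }
  hits
}
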