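## ---- toy germline -------------------------------------------------------

## V region template used by the toy set (nt): FR1 78 (26 aa, first-Cys at
## aa 23), CDR1 24, FR2 51, CDR2 24, FR3 114 (ends with the second-Cys
## codon), then a 10-nt junction-forming 3' tail.
TOY_V_BOUNDS <- list(FR1 = c(0L, 78L), CDR1 = c(78L, 102L),
                     FR2 = c(102L, 153L), CDR2 = c(153L, 177L),
                     FR3 = c(177L, 291L))
TOY_V_TAIL_LEN <- 10L

#' Build a small deterministic germline set for simulation and testing
#'
#' The heavy-chain set has six functional V genes in two clans (members of
#' a clan are ~95% identical over FR1-FR3), one ORF V (second-Cys codon
#' mutated to Ser), one pseudogene V (internal stop in FR2), four D genes
#' including one long (YG)n-rich segment for ultra-long CDR3H simulation,
#' and three J genes of which one lacks the WGXG motif (pseudogene). The
#' light-chain (IGK) set has four functional V in two clans and three J
#' (FGXG motif; one pseudogene without it). Base composition is
#' near-uniform by construction so that simulated substitution spectra are
#' realized at their configured marginal weights.
#'
#' @param seed integer seed (default 42); the same seed always yields the
#'   byte-identical set.
#' @param locus `"IGH"` or `"IGK"`.
#' @return a `GermlineSet` with functionality and clan labels filled in.
#' @export
make_toy_germline <- function(seed = 42L, locus = c("IGH", "IGK")) {
  locus <- match.arg(locus)
  with_seed(seed + ifelse(locus == "IGH", 0L, 1000L), {
    if (locus == "IGH") toy_igh_set() else toy_igk_set()
  })
}

## run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## random in-frame stop-free DNA of length n (multiple of 3)
random_orf <- function(n) {
  stopifnot(n %% 3L == 0L)
  codons <- character(n %/% 3L)
  for (i in seq_along(codons)) {
    repeat {
      cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## derive a clan member: mutate `k` positions of the core, never touching
## the two conserved Cys codons and never creating an in-frame stop
mutate_core <- function(core, k) {
  protected <- c(67:69, 289:291)   # 1-based Cys codon positions
  v <- chars(core)
  pos <- sample(setdiff(seq_along(v), protected), k)
  for (p in pos) {
    repeat {
      nb <- sample(setdiff(BASES, v[p]), 1L)
      old <- v[p]; v[p] <- nb
      codon_i <- (p - 1L) %/% 3L
      codon <- paste(v[(codon_i * 3L + 1L):(codon_i * 3L + 3L)], collapse = "")
      if (!codon %in% STOP_CODONS) break
      v[p] <- old
    }
  }
  paste(v, collapse = "")
}

toy_core_seed <- function() {
  core <- random_orf(291L)
  substr(core, 67L, 69L) <- "TGT"    # first-Cys (aa 23 of FR1)
  substr(core, 289L, 291L) <- "TGT"  # second-Cys (last FR3 codon)
  core
}

toy_igh_set <- function() {
  seedA <- toy_core_seed(); seedB <- toy_core_seed()
  cores <- c(lapply(c(0L, 12L, 14L), function(k)
               if (k == 0L) seedA else mutate_core(seedA, k)),
             lapply(c(0L, 12L, 14L), function(k)
               if (k == 0L) seedB else mutate_core(seedB, k)))
  vs <- lapply(seq_along(cores), function(i) {
    germline_gene(sprintf("IGHV%d", i), "IGH", "V",
                  paste0(cores[[i]], random_dna(TOY_V_TAIL_LEN)),
                  region_bounds = TOY_V_BOUNDS)
  })
  ## ORF: second-Cys codon TGT -> AGT (Ser)
  orf_core <- cores[[1L]]
  substr(orf_core, 289L, 289L) <- "A"
  v7 <- germline_gene("IGHV7", "IGH", "V",
                      paste0(orf_core, random_dna(TOY_V_TAIL_LEN)),
                      region_bounds = TOY_V_BOUNDS)
  ## pseudogene: TAA introduced mid-FR2 (codon starting at nt 121)
  pse_core <- cores[[1L]]
  substr(pse_core, 121L, 123L) <- "TAA"
  v8 <- germline_gene("IGHV8", "IGH", "V",
                      paste0(pse_core, random_dna(TOY_V_TAIL_LEN)),
                      region_bounds = TOY_V_BOUNDS)
  ds <- list(
    germline_gene("IGHD1", "IGH", "D", random_dna(16L)),
    germline_gene("IGHD2", "IGH", "D", random_dna(18L)),
    germline_gene("IGHD3", "IGH", "D", random_dna(20L)),
    germline_gene("IGHD4", "IGH", "D", strrep("TATGGT", 18L)))  # (YG)n
  js <- list(
    germline_gene("IGHJ1", "IGH", "J",
                  paste0(random_dna(12L), "TGGGGCCAAGGGACCCAGGTCACCGTCTCCTCA")),
    germline_gene("IGHJ2", "IGH", "J",
                  paste0(random_dna(12L), "TGGGGCCAGGGAACCCTGGTCACTGTGTCTTCA")),
    ## pseudogene: no TGG anywhere, so no W-G-X-G in any frame; body kept
    ## well apart from the functional J bodies so trimmed reads stay
    ## assignable
    germline_gene("IGHJ3", "IGH", "J",
                  paste0(random_dna(12L), "TCCGGACAAGCGACCCTAGTCACCGTCTCCTCA")))
  finalize_toy_set(c(vs, list(v7, v8), ds, js), "IGH")
}

toy_igk_set <- function() {
  seedA <- toy_core_seed(); seedB <- toy_core_seed()
  cores <- list(seedA, mutate_core(seedA, 13L), seedB, mutate_core(seedB, 13L))
  vs <- lapply(seq_along(cores), function(i) {
    germline_gene(sprintf("IGKV%d", i), "IGK", "V",
                  paste0(cores[[i]], random_dna(TOY_V_TAIL_LEN)),
                  region_bounds = TOY_V_BOUNDS)
  })
  js <- list(
    germline_gene("IGKJ1", "IGK", "J",
                  paste0(random_dna(10L), "TTTGGCCAAGGGACCAAGGTGGAAATCAAA")),
    germline_gene("IGKJ2", "IGK", "J",
                  paste0(random_dna(10L), "TTCGGCCAGGGAACCAAACTGGAGATTAAA")),
    ## pseudogene: no TTT/TTC codon start, so no F-G-X-G in any frame
    germline_gene("IGKJ3", "IGK", "J",
                  paste0(random_dna(10L), "AGACCGCAAGGGACCAAGCTGGAGCTGAAA")))
  finalize_toy_set(c(vs, js), "IGK")
}

## classify everything and attach clan labels
finalize_toy_set <- function(genes, locus) {
  classify_germline_set(germline_set(genes, locus = locus,
                                     metadata = list(source = "igjunction toy set")))
}

## ---- simulation config --------------------------------------------------

#' Simulation configuration for the V(D)J read generator
#'
#' Defaults encode the junctional statistics the annotation pipeline
#' assumes: V 3' trimming concentrated at 0/2/3 bp (max 8), J 5' trimming
#' at 0/3/6 bp (max 12) for heavy chains; light-chain trims mainly 0-3 bp;
#' P insertions only at untrimmed ends and short (0-2 bp); N insertions
#' short for light chains and longer for heavy chains; SHM with an A<->G
#' transition bias and AID-hotspot (WRCY/RGYW) enrichment; and a heavily
#' biased J usage (0.95/0.04/0.01). All distributions are overridable
#' empirical tables (names = lengths, values = probabilities).
#'
#' @param locus `"IGH"` or `"IGK"`.
#' @param germline_set a `GermlineSet`; default [make_toy_germline()].
#' @param n_reads number of reads.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @param v_weights,d_weights,j_weights named segment-usage weights
#'   (default: uniform over functional V, the listed D defaults, and the
#'   biased J table).
#' @param v_del_dist,j_del_dist,d_del5_dist,d_del3_dist trimming tables.
#' @param p_len_dist,n_len_dist insertion-length tables.
#' @param shm_rate per-base mutation probability over FR1-FR3 (default 0.05).
#' @param cdr_rate_multiplier CDR1/CDR2 rate multiplier (default 3).
#' @param hotspot_multiplier hotspot-position rate multiplier (default 5).
#' @param hotspot_motifs motifs defining hotspot positions.
#' @param spectrum_weights named 12-class substitution weights
#'   (`"A>G"` etc.); marginal substitution-class fractions are realized at
#'   these weights under uniform base composition.
#' @param seq_error_rate additional uniform error channel (default 0; SHM
#'   and sequencing error are otherwise conflated in `shm_rate`).
#' @param ultralong_fraction fraction of reads forced onto the ultra-long
#'   D template (IGH only; default 0).
#' @param ultralong_d gene id of the (YG)n-rich D.
#' @param decorate prepend/append primers and constant-region stub
#'   (default TRUE).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(locus = c("IGH", "IGK"), germline_set = NULL,
                       n_reads = 1000L, seed = 1L,
                       v_weights = NULL, d_weights = NULL, j_weights = NULL,
                       v_del_dist = NULL, j_del_dist = NULL,
                       d_del5_dist = NULL, d_del3_dist = NULL,
                       p_len_dist = NULL, n_len_dist = NULL,
                       shm_rate = 0.05, cdr_rate_multiplier = 3,
                       hotspot_multiplier = 5,
                       hotspot_motifs = c("WRCY", "RGYW"),
                       spectrum_weights = NULL, seq_error_rate = 0,
                       ultralong_fraction = 0, ultralong_d = "IGHD4",
                       decorate = TRUE) {
  locus <- match.arg(locus)
  if (is.null(germline_set)) germline_set <- make_toy_germline(locus = locus)
  defaults <- sim_defaults(locus)
  pick <- function(x, d) if (is.null(x)) d else x
  fv <- Filter(function(g) g$functionality == "functional",
               genes_of_type(germline_set, "V"))
  if (is.null(v_weights)) {
    v_weights <- stats::setNames(rep(1 / length(fv), length(fv)),
                                 sort(names(fv)))
  }
  if (is.null(j_weights)) {
    js <- sort(names(genes_of_type(germline_set, "J")))
    j_weights <- stats::setNames(defaults$j_weights[seq_along(js)], js)
  }
  if (is.null(d_weights) && locus == "IGH") {
    ds <- sort(names(genes_of_type(germline_set, "D")))
    d_weights <- stats::setNames(defaults$d_weights[seq_along(ds)], ds)
  }
  cfg <- list(
    locus = locus, germline_set = germline_set,
    n_reads = as.integer(n_reads), seed = as.integer(seed),
    v_weights = v_weights / sum(v_weights),
    d_weights = if (!is.null(d_weights)) d_weights / sum(d_weights),
    j_weights = j_weights / sum(j_weights),
    v_del_dist = pick(v_del_dist, defaults$v_del),
    j_del_dist = pick(j_del_dist, defaults$j_del),
    d_del5_dist = pick(d_del5_dist, defaults$d_del),
    d_del3_dist = pick(d_del3_dist, defaults$d_del),
    p_len_dist = pick(p_len_dist, defaults$p_len),
    n_len_dist = pick(n_len_dist, defaults$n_len),
    shm_rate = shm_rate, cdr_rate_multiplier = cdr_rate_multiplier,
    hotspot_multiplier = hotspot_multiplier, hotspot_motifs = hotspot_motifs,
    spectrum_weights = pick(spectrum_weights, default_spectrum()),
    seq_error_rate = seq_error_rate,
    ultralong_fraction = ultralong_fraction, ultralong_d = ultralong_d,
    decorate = decorate, decoration = decoration_for(locus))
  cfg$spectrum_weights <- cfg$spectrum_weights / sum(cfg$spectrum_weights)
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

## trimming / insertion defaults per locus (empirical tables: modes and
## maxima as observed in expressed bovid repertoires)
sim_defaults <- function(locus) {
  tb <- function(...) { x <- c(...); x / sum(x) }
  if (locus == "IGH") {
    list(
      v_del = tb("0" = .30, "1" = .08, "2" = .22, "3" = .22, "4" = .06,
                 "5" = .04, "6" = .04, "7" = .02, "8" = .02),
      j_del = tb("0" = .26, "1" = .04, "2" = .04, "3" = .20, "4" = .12,
                 "5" = .04, "6" = .16, "7" = .04, "8" = .04, "9" = .02,
                 "10" = .02, "11" = .01, "12" = .01),
      d_del = tb("0" = .45, "1" = .25, "2" = .15, "3" = .10, "4" = .05),
      p_len = tb("0" = .55, "1" = .30, "2" = .15),
      n_len = tb("0" = .12, "1" = .16, "2" = .18, "3" = .16, "4" = .12,
                 "5" = .10, "6" = .08, "7" = .05, "8" = .03),
      j_weights = c(.95, .04, .01),
      d_weights = c(.15, .40, .40, .05))
  } else {
    list(
      v_del = tb("0" = .15, "1" = .28, "2" = .28, "3" = .22, "4" = .05,
                 "5" = .02),
      j_del = tb("0" = .15, "1" = .28, "2" = .28, "3" = .22, "4" = .05,
                 "5" = .02),
      d_del = NULL,
      p_len = tb("0" = .65, "1" = .30, "2" = .05),
      n_len = tb("0" = .55, "1" = .35, "2" = .10),
      j_weights = c(.70, .25, .05),
      d_weights = NULL)
  }
}

## transition-biased 12-class defaults (A<->G highest, then C<->T)
default_spectrum <- function() {
  w <- c("A>G" = .18, "G>A" = .18, "C>T" = .14, "T>C" = .14)
  tv <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  tv <- tv[tv$from != tv$to, ]
  keys <- paste0(tv$from, ">", tv$to)
  out <- stats::setNames(rep(.36 / 8, 12L), keys)
  out[names(w)] <- w
  out
}

## 5'-RACE style decoration: universal forward primer, locus-specific
## reverse primer annealing in a constant-region stub
decoration_for <- function(locus) {
  rev_primer <- c(IGH = "AGCTCACGCAGGACACCAG",
                  IGK = "AGATGGATGGCTGAGCATCA",
                  IGL = "GTGACCGAGGGTGCGGACTT")[[locus]]
  const <- c(
    IGH = "GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACCTCTGG",
    IGK = "CGAACTGTGGCTGCACCATCTGTCTTCATCTTCCCGCCATCTGATGAGCAGTTGAAATC",
    IGL = "GGTCAGCCCAAGGCTGCCCCCTCGGTCACTCTGTTCCCGCCCTCCTCTGAGGAGCTTCA")[[locus]]
  list(forward_primer = "AAGCAGTGGTATCAACGCAGAGT",
       reverse_primer = rev_primer,
       constant_region = const)
}

validate_sim_config <- function(cfg) {
  set <- cfg$germline_set
  vs <- set$genes[names(cfg$v_weights)]
  tails <- vapply(vs, function(g) nchar(v_tail_seq(g)), integer(1L))
  if (max(as.integer(names(cfg$v_del_dist))) > min(tails)) {
    stop("v_del_dist: deletion support exceeds the V 3' tail length")
  }
  js <- genes_of_type(set, "J")
  heads <- vapply(js, function(g) {
    jc <- classify_j_gene(g)
    if (is.na(jc$frame)) nchar(g$nt_sequence)
    else jc$frame + (jc$motif_aa_start - 1L) * 3L
  }, integer(1L))
  if (max(as.integer(names(cfg$j_del_dist))) > min(heads[names(cfg$j_weights)])) {
    stop("j_del_dist: deletion support exceeds the J 5' head length")
  }
  if (!is.null(cfg$d_weights)) {
    ds <- set$genes[names(cfg$d_weights)]
    dl <- vapply(ds, function(g) nchar(g$nt_sequence), integer(1L))
    span <- max(as.integer(names(cfg$d_del5_dist))) +
      max(as.integer(names(cfg$d_del3_dist)))
    if (span >= min(dl)) {
      stop("d_del5_dist/d_del3_dist: combined deletion support exceeds the shortest D")
    }
  }
  invisible(cfg)
}

## ---- the generator ------------------------------------------------------

draw_table <- function(dist) {
  as.integer(sample(names(dist), 1L, prob = dist))
}

#' Simulate a V(D)J-rearranged, somatically mutated repertoire
#'
#' Per read: draw segments by weight, trim ends per the configured
#' distributions, add P nucleotides (reverse complement of the terminal
#' retained bases, only at untrimmed ends), add N nucleotides (uniform
#' composition), assemble, apply SHM (per-base Bernoulli over FR1-FR3 with
#' CDR and hotspot multipliers; substitution class drawn from the spectrum
#' weights) and decorate with primers and a constant-region stub. Ground
#' truth is recorded before decoration-independent fields are lost;
#' replaying a truth row against the germline set reproduces the read
#' byte-exactly (see [replay_truth()]).
#'
#' @param config a `SimulationConfig` from [sim_config()].
#' @return list with `reads` (named character vector), `truth`
#'   (data.frame, one row per read) and `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set <- config$germline_set
  shm_tables <- shm_rate_tables(config)
  with_seed(config$seed, {
    rows <- vector("list", config$n_reads)
    reads <- character(config$n_reads)
    ids <- sprintf("read%05d", seq_len(config$n_reads))
    for (i in seq_len(config$n_reads)) {
      sim <- simulate_one(config, set, shm_tables)
      reads[i] <- sim$read
      rows[[i]] <- cbind(data.frame(read_id = ids[i], stringsAsFactors = FALSE),
                         sim$truth)
    }
    names(reads) <- ids
    list(reads = reads, truth = do.call(rbind, rows), config = config)
  })
}

simulate_one <- function(cfg, set, shm_tables) {
  v_id <- sample(names(cfg$v_weights), 1L, prob = cfg$v_weights)
  j_id <- sample(names(cfg$j_weights), 1L, prob = cfg$j_weights)
  v <- set$genes[[v_id]]; j <- set$genes[[j_id]]
  vseq <- v$nt_sequence; jseq <- j$nt_sequence

  v_del <- draw_table(cfg$v_del_dist)
  j_del <- draw_table(cfg$j_del_dist)
  v_ret <- substr(vseq, 1L, nchar(vseq) - v_del)
  j_ret <- substr(jseq, j_del + 1L, nchar(jseq))

  p1 <- if (v_del == 0L) make_p(vseq, draw_table(cfg$p_len_dist), end = "3p") else ""
  p2 <- if (j_del == 0L) make_p(jseq, draw_table(cfg$p_len_dist), end = "5p") else ""

  d_id <- NA_character_; d_ret <- ""; d_del5 <- NA_integer_; d_del3 <- NA_integer_
  p_d5 <- ""; p_d3 <- ""; n2 <- ""
  ultralong <- FALSE
  if (!is.null(cfg$d_weights)) {
    if (cfg$ultralong_fraction > 0 && stats::runif(1L) < cfg$ultralong_fraction) {
      d_id <- cfg$ultralong_d; ultralong <- TRUE
    } else {
      d_id <- sample(names(cfg$d_weights), 1L, prob = cfg$d_weights)
    }
    dseq <- set$genes[[d_id]]$nt_sequence
    repeat {
      d_del5 <- draw_table(cfg$d_del5_dist)
      d_del3 <- draw_table(cfg$d_del3_dist)
      if (d_del5 + d_del3 < nchar(dseq)) break
    }
    d_ret <- substr(dseq, d_del5 + 1L, nchar(dseq) - d_del3)
    p_d5 <- if (d_del5 == 0L) make_p(dseq, draw_table(cfg$p_len_dist), end = "5p") else ""
    p_d3 <- if (d_del3 == 0L) make_p(dseq, draw_table(cfg$p_len_dist), end = "3p") else ""
    n2 <- random_dna(draw_table(cfg$n_len_dist))
  }
  n1 <- random_dna(draw_table(cfg$n_len_dist))

  body <- paste0(v_ret, p1, n1, p_d5, d_ret, p_d3, n2, p2, j_ret)

  ## SHM over the V FR1-FR3 core of the assembled read
  shm <- apply_shm(body, cfg, shm_tables[[v_id]])
  body <- shm$seq

  dec <- cfg$decoration
  read <- if (cfg$decorate) {
    paste0(dec$forward_primer, body, dec$constant_region,
           revcomp(dec$reverse_primer))
  } else body
  if (cfg$seq_error_rate > 0) read <- uniform_errors(read, cfg$seq_error_rate)

  offset <- if (cfg$decorate) nchar(dec$forward_primer) else 0L
  fr3_end <- v$region_bounds$FR3[2]
  cdr3_start <- offset + fr3_end                       # 0-based, after the Cys codon
  jc <- classify_j_gene(j)
  anchor0 <- if (!is.na(jc$frame)) jc$frame + (jc$motif_aa_start - 1L) * 3L else NA_integer_
  j_read_start <- offset + nchar(v_ret) + nchar(p1) + nchar(n1) +
    nchar(p_d5) + nchar(d_ret) + nchar(p_d3) + nchar(n2) + nchar(p2)
  cdr3_end <- if (!is.na(anchor0)) j_read_start + (anchor0 - j_del) else NA_integer_

  truth <- data.frame(
    v_call = v_id, d_call = d_id, j_call = j_id,
    v_deletion = v_del, j_deletion = j_del,
    d_deletion_5p = d_del5, d_deletion_3p = d_del3,
    p1 = p1, n1 = n1, p_d5 = p_d5, p_d3 = p_d3, n2 = n2, p2 = p2,
    cdr3_start = cdr3_start, cdr3_end = cdr3_end,
    shm_events = paste(shm$events, collapse = ";"), n_shm = length(shm$events),
    ultralong = ultralong, sequence = read, stringsAsFactors = FALSE)
  list(read = read, truth = truth)
}

## P nucleotides mirrored off an untrimmed coding end
make_p <- function(germline, len, end = c("3p", "5p")) {
  end <- match.arg(end)
  if (len == 0L) return("")
  L <- nchar(germline)
  if (end == "3p") revcomp(substr(germline, L - len + 1L, L))
  else revcomp(substr(germline, 1L, len))
}

## Precomputed per-gene SHM rate tables. Rates are
## shm_rate * 4 * w_out(base) * multipliers, so the marginal
## substitution-class fractions equal spectrum_weights under uniform base
## composition (and the mean rate equals shm_rate exactly for a uniform
## spectrum). Positions are 0-based on the germline gene; in the assembled
## read body the core occupies the same coordinates (the full germline V 5'
## region is always retained).
shm_rate_tables <- function(cfg) {
  if (cfg$shm_rate <= 0) return(list())
  w <- cfg$spectrum_weights
  w_out <- vapply(BASES, function(bb)
    sum(w[startsWith(names(w), paste0(bb, ">"))]), numeric(1L))
  set <- cfg$germline_set
  out <- list()
  for (v_id in names(cfg$v_weights)) {
    g <- set$genes[[v_id]]
    b <- g$region_bounds
    core <- v_core_seq(g)
    cv <- chars(core)
    core_start <- b$FR1[1]
    rate <- cfg$shm_rate * 4 * unname(w_out[match(cv, BASES)])
    rate[is.na(rate)] <- 0
    pos0 <- seq_along(cv) - 1L + core_start
    in_cdr <- (pos0 >= b$CDR1[1] & pos0 < b$CDR1[2]) |
      (pos0 >= b$CDR2[1] & pos0 < b$CDR2[2])
    rate[in_cdr] <- rate[in_cdr] * cfg$cdr_rate_multiplier
    hot <- unique(unlist(lapply(cfg$hotspot_motifs, function(m)
      hotspot_positions(core, m))))
    rate[pos0 %in% (hot + core_start)] <- rate[pos0 %in% (hot + core_start)] *
      cfg$hotspot_multiplier
    out[[v_id]] <- list(pos0 = pos0, base = cv, rate = pmin(rate, 0.95))
  }
  out
}

## per-base Bernoulli SHM over the V core of the assembled read
apply_shm <- function(body, cfg, tab) {
  if (is.null(tab)) return(list(seq = body, events = character(0L)))
  hits <- which(stats::runif(length(tab$rate)) < tab$rate)
  if (!length(hits)) return(list(seq = body, events = character(0L)))
  v <- chars(body)
  w <- cfg$spectrum_weights
  events <- character(length(hits))
  for (k in seq_along(hits)) {
    i <- hits[k]
    base <- tab$base[i]
    others <- setdiff(BASES, base)
    to <- sample(others, 1L, prob = w[paste0(base, ">", others)])
    ri <- tab$pos0[i] + 1L
    v[ri] <- to
    events[k] <- sprintf("%d:%s>%s", tab$pos0[i], base, to)
  }
  list(seq = paste(v, collapse = ""), events = events)
}

uniform_errors <- function(read, rate) {
  v <- chars(read)
  hit <- which(stats::runif(length(v)) < rate & v %in% BASES)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1L)
  paste(v, collapse = "")
}

#' Replay a ground-truth row into a read sequence
#'
#' Reassembles the read from the germline set and the recorded segment
#' choices, trims, P/N strings and SHM events; used to assert that the
#' truth table fully determines every emitted read.
#'
#' @param truth_row one row of the truth data.frame.
#' @param config the `SimulationConfig` used for the run.
#' @return the reconstructed read (character scalar).
#' @export
replay_truth <- function(truth_row, config) {
  set <- config$germline_set
  v <- set$genes[[truth_row$v_call]]
  j <- set$genes[[truth_row$j_call]]
  v_ret <- substr(v$nt_sequence, 1L, nchar(v$nt_sequence) - truth_row$v_deletion)
  j_ret <- substr(j$nt_sequence, truth_row$j_deletion + 1L, nchar(j$nt_sequence))
  d_ret <- ""
  if (!is.na(truth_row$d_call)) {
    dseq <- set$genes[[truth_row$d_call]]$nt_sequence
    d_ret <- substr(dseq, truth_row$d_deletion_5p + 1L,
                    nchar(dseq) - truth_row$d_deletion_3p)
  }
  body <- paste0(v_ret, truth_row$p1, truth_row$n1, truth_row$p_d5, d_ret,
                 truth_row$p_d3, truth_row$n2, truth_row$p2, j_ret)
  if (nzchar(truth_row$shm_events)) {
    for (ev in strsplit(truth_row$shm_events, ";", fixed = TRUE)[[1L]]) {
      m <- regmatches(ev, regexec("^(\\d+):([ACGT])>([ACGT])$", ev))[[1L]]
      pos <- as.integer(m[2L]) + 1L
      stopifnot(substr(body, pos, pos) == m[3L] || substr(body, pos, pos) == m[2L])
      substr(body, pos, pos) <- m[4L]
    }
  }
  dec <- config$decoration
  if (config$decorate) {
    paste0(dec$forward_primer, body, dec$constant_region,
           revcomp(dec$reverse_primer))
  } else body
}
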