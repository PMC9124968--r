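# build a minimal record with a chosen set of substitutions against a toy V
mutated_record <- function(gene, positions, to = NULL, id = "r1") {
  core <- igjunction:::v_core_seq(gene)
  read <- core
  for (k in seq_along(positions)) {
    p <- positions[k]
    from <- substr(read, p, p)
    nb <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), from)[1L] else to[k]
    substr(read, p, p) <- nb
  }
  read <- paste0(read, random_seq(30))
  call <- assign_v(read, germline_set(list(gene), locus = gene$locus),
                   functional_only = FALSE)
  structure(list(read_id = id, sequence = read, v_call = call,
                 cdr3 = NULL, junction_decomposition = NULL),
            class = "RearrangementRecord")
}

test_that("SHM frequency implements mutated / covered bases as a percentage", {
  set.seed(51)
  gene <- toy_igh$genes$IGHV1          # 291 aligned core bases
  rec3 <- mutated_record(gene, c(10L, 50L, 200L))
  ## one extra exactly-germline read dilutes the denominator
  rec0 <- mutated_record(gene, integer(0L), id = "r2")
  res <- shm_frequency(list(rec3))
  expect_equal(res$overall_pct, 100 * 3 / 291)
  expect_equal(shm_frequency(list(rec0))$overall_pct, 0)
  both <- shm_frequency(list(rec3, rec0))
  expect_equal(both$overall_pct, 100 * 3 / (2 * 291))
  expect_equal(both$per_gene$pct, 100 * 3 / (2 * 291))
})

test_that("SHM frequency warns and returns NA with no covered bases", {
  expect_warning(res <- shm_frequency(list()), "no covered bases")
  expect_true(is.na(res$overall_pct))
})

test_that("a planted per-site hotspot shows frequency 1 there and 0 elsewhere", {
  set.seed(52)
  gene <- toy_igh$genes$IGHV2
  recs <- lapply(1:10, function(i)
    mutated_record(gene, 58L, id = sprintf("r%d", i)))  # germline position 57 (0-based)
  prof <- per_site_profile(recs, toy_igh)[[1L]]
  expect_equal(prof$frequency[prof$germline_position == 57L], 1)
  expect_true(all(prof$frequency[prof$germline_position != 57L] == 0))
  expect_true(all(prof$coverage == 10L))
  expect_equal(prof$region[prof$germline_position == 0L], "FR1")
  expect_equal(prof$region[prof$germline_position == 290L], "FR3")
})

test_that("profile mutation totals conserve the assignment mutation totals", {
  cfg <- sim_config(n_reads = 80, seed = 53)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  elig <- Filter(function(r) !is.null(r$v_call) && !r$v_call$ambiguous, recs)
  profs <- per_site_profile(recs, cfg$germline_set)
  expect_equal(sum(vapply(profs, function(p) sum(p$mutations), numeric(1L))),
               sum(vapply(elig, function(r)
                 nrow(r$v_call$best$mutated_positions), numeric(1L))))
  ## overall frequency equals the coverage-weighted mean of site frequencies
  freq <- shm_frequency(recs)
  num <- sum(vapply(profs, function(p) sum(p$mutations), numeric(1L)))
  den <- sum(vapply(profs, function(p) sum(p$coverage), numeric(1L)))
  expect_equal(freq$overall_pct, 100 * num / den)
})

test_that("the substitution spectrum counts classes and normalizes to 100%", {
  set.seed(54)
  gene <- toy_igh$genes$IGHV1
  core <- igjunction:::v_core_seq(gene)
  a_pos <- which(strsplit(core, "")[[1L]] == "A")[1L]
  rec <- mutated_record(gene, a_pos, to = "G")
  spec <- substitution_spectrum(list(rec))
  expect_equal(spec$percent[spec$from == "A" & spec$to == "G"], 100)
  expect_equal(sum(spec$count), 1L)
  expect_equal(sum(spec$percent), 100)

  empty <- substitution_spectrum(list())
  expect_true(all(empty$count == 0L))
  expect_true(all(is.na(empty$percent)))
})

test_that("spectrum percentages always sum to 100 on simulated data", {
  cfg <- sim_config(n_reads = 60, seed = 55)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  spec <- substitution_spectrum(recs)
  expect_equal(sum(spec$percent), 100, tolerance = 1e-9)
  expect_equal(nrow(spec), 12L)
})

test_that("hotspot position scanning equals a brute-force IUPAC regex oracle", {
  set.seed(56)
  iupac_expand <- list(W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
                       D = c("A", "G", "T"), H = c("A", "C", "T"))
  brute <- function(seq, motif, offset) {
    v <- strsplit(seq, "")[[1L]]
    m <- strsplit(motif, "")[[1L]]
    hits <- integer(0L)
    for (s in seq_len(length(v) - 3L)) {
      ok <- all(vapply(1:4, function(k) {
        allowed <- if (m[k] %in% names(iupac_expand)) iupac_expand[[m[k]]] else m[k]
        v[s + k - 1L] %in% allowed
      }, logical(1L)))
      if (ok) hits <- c(hits, s - 1L + offset)
    }
    hits
  }
  for (rep in 1:10) {
    seq <- random_seq(200)
    expect_equal(hotspot_positions(seq, "WRCY"), brute(seq, "WRCY", 2L))
    expect_equal(hotspot_positions(seq, "RGYW"), brute(seq, "RGYW", 1L))
    expect_equal(hotspot_positions(seq, "DGYW"), brute(seq, "DGYW", 1L))
    expect_equal(hotspot_positions(seq, "WRCH"), brute(seq, "WRCH", 2L))
  }
})

test_that("hotspot mutation frequencies are counted per substitution class", {
  set.seed(57)
  gene <- toy_igh$genes$IGHV3
  core <- igjunction:::v_core_seq(gene)
  hot <- hotspot_positions(core, "WRCY")
  expect_gt(length(hot), 0L)   # the toy gene carries WRCY sites
  p1 <- hot[1L] + 1L           # 1-based position of a hotspot C
  recs <- c(lapply(1:4, function(i)
              mutated_record(gene, p1, to = "T", id = sprintf("m%d", i))),
            lapply(5:10, function(i)
              mutated_record(gene, integer(0L), id = sprintf("m%d", i))))
  rep <- hotspot_analysis(recs, toy_igh, motif_set = "WRCY")$WRCY
  expect_equal(rep$n_hotspot_positions, length(hot))
  ## 4 C->T mutations over 10 reads x n_hot covered positions
  expect_equal(rep$hotspot$mutations, 4L)
  expect_equal(rep$hotspot$coverage, 10L * length(hot))
  expect_equal(rep$hotspot$frequency, 4 / (10 * length(hot)))
  expect_equal(unname(rep$hotspot$by_substitution["T"]),
               4 / (10 * length(hot)))
  expect_equal(rep$baseline$mutations, 0L)
  expect_true(is.na(rep$enrichment))   # baseline frequency is 0
})

test_that("an empty motif set is rejected", {
  expect_error(hotspot_analysis(list(), toy_igh, motif_set = character(0L)),
               "empty motif set")
  expect_error(hotspot_analysis(list(), toy_igh, motif_set = "XYZW"), "unknown")
})

test_that("ambiguous V calls are excluded from SHM statistics by default", {
  g1 <- toy_igh$genes$IGHV1
  twin <- g1; twin$gene_id <- "IGHV1b"
  set2 <- germline_set(list(g1, twin,
                            toy_igh$genes$IGHJ1), locus = "IGH")
  read <- paste0(igjunction:::v_core_seq(g1), random_seq(30))
  call <- assign_v(read, set2, functional_only = FALSE)
  rec <- structure(list(read_id = "t", sequence = read, v_call = call),
                   class = "RearrangementRecord")
  expect_warning(res <- shm_frequency(list(rec)))
  expect_true(is.na(res$overall_pct))
  res2 <- shm_frequency(list(rec), include_ambiguous = TRUE)
  expect_equal(res2$overall_pct, 0)
})
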