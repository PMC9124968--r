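test_that("a blunt V-J join decomposes with no trims, P or N", {
  set.seed(41)
  vseq <- paste0(substr(igjunction:::toy_core_seed(), 1, 12), random_seq(8))
  jseq <- random_seq(20)
  set <- make_micro_set(vseq, jseq)
  res <- micro_decompose(set, v_del = 0L, j_del = 0L, insert = "")
  dec <- res$dec
  ## blunt joins can only be reported blunt when no end base mirrors across;
  ## assert against the enumeration oracle instead of assuming
  want <- junction_oracle(set, 0L, 0L, "")
  expect_equal(dec$v_deletion, want$v_deletion)
  expect_equal(dec$j_deletion, want$j_deletion)
  expect_equal(dec$p1, want$p1)
  expect_equal(dec$p2, want$p2)
  expect_equal(dec$n1, want$n)
})

test_that("a constructed palindromic overhang is attributed as P then N", {
  ## germline V ends ...GATTC (untrimmed); insert GA = revcomp(TC), then T
  vseq <- paste0("ACGACGACGACG", "CCG", "GATTC")   # 20 nt, core = first 12
  jseq <- paste0("ATCCTG", "AGCGTAGCATCGAT")       # 20 nt
  set <- make_micro_set(vseq, jseq)
  res <- micro_decompose(set, v_del = 0L, j_del = 3L, insert = "GAT")
  dec <- res$dec
  expect_equal(dec$v_deletion, 0L)
  expect_equal(dec$p1, "GA")
  expect_equal(dec$n1, "T")
  expect_equal(dec$p2, "")
  expect_equal(dec$j_deletion, 3L)
})

test_that("decomposition equals the exhaustive enumeration oracle on a micro grid", {
  set.seed(43)
  vseq <- "ACGACGACGACGCCGGATTC"
  jseq <- "ATCCTGAGCGTAGCATCGAT"
  set <- make_micro_set(vseq, jseq)
  inserts <- all_inserts(2L)          # lengths 0..2 here; the full grid runs
  for (v_del in 0:4) for (j_del in 0:4) {  # in the acceptance suite
    for (ins in inserts) {
      dec <- micro_decompose(set, v_del, j_del, ins)$dec
      want <- junction_oracle(set, v_del, j_del, ins)
      lab <- sprintf("v_del=%d j_del=%d ins=%s", v_del, j_del, ins)
      expect_equal(dec$v_deletion, want$v_deletion, info = lab)
      expect_equal(dec$j_deletion, want$j_deletion, info = lab)
      expect_equal(dec$p1, want$p1, info = lab)
      expect_equal(dec$p2, want$p2, info = lab)
      expect_equal(dec$n1, want$n, info = lab)
    }
  }
})

test_that("the reconstruction and P-legality invariants hold on simulated data", {
  cfg <- sim_config(n_reads = 60, seed = 31)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  for (r in recs) {
    dec <- r$junction_decomposition
    if (is.null(dec)) next
    window <- substr(r$sequence, dec$v_read_end + 1L, dec$j_read_start)
    rebuilt <- paste0(dec$p1, dec$n1, dec$p_d5, dec$retained_d, dec$p_d3,
                      dec$n2, dec$p2)
    expect_identical(rebuilt, window)
    if (nchar(dec$p1)) expect_equal(dec$v_deletion, 0L)
    if (nchar(dec$p2)) expect_equal(dec$j_deletion, 0L)
  }
})

test_that("CDR3 anchors are placed by projection, surviving anchor-codon SHM", {
  cfg <- sim_config(n_reads = 30, seed = 33, shm_rate = 0)
  sim <- simulate_repertoire(cfg)
  reads <- sim$reads
  recs <- annotate_reads(reads, cfg$germline_set)
  cmp <- truth_comparison(recs, sim$truth)
  usable <- !is.na(sim$truth$cdr3_end)
  expect_true(all(cmp$cdr3_ok[usable]))

  ## mutate the anchor C codon TGT -> AGT on one read: interval must not move
  i <- which(usable)[1L]
  read <- reads[[i]]
  c_pos <- sim$truth$cdr3_start[i] - 3L   # 0-based start of the Cys codon
  expect_equal(substr(read, c_pos + 1L, c_pos + 3L), "TGT")
  substr(read, c_pos + 1L, c_pos + 1L) <- "A"
  rec <- annotate_reads(stats::setNames(read, "m"), cfg$germline_set)[[1L]]
  expect_false(rec$cdr3_missing)
  expect_equal(rec$cdr3$nt_start, sim$truth$cdr3_start[i])
  expect_equal(rec$cdr3$nt_end, sim$truth$cdr3_end[i])
  expect_equal(rec$cdr3$anchor_mismatches, 1L)
})

test_that("records rearranged onto an anchorless J are flagged cdr3_missing", {
  cfg <- sim_config(n_reads = 12, seed = 35, shm_rate = 0,
                    j_weights = c(IGHJ3 = 1))
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  expect_true(all(vapply(recs, function(r) r$cdr3_missing, logical(1L))))
})

test_that("in-frame CDR3 nucleotide length is three times the AA length", {
  cfg <- sim_config(n_reads = 50, seed = 37)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  for (r in recs) {
    if (is.null(r$cdr3) || !r$cdr3$in_frame) next
    expect_equal(nchar(r$cdr3$nt_sequence), 3L * nchar(r$cdr3$aa_sequence))
  }
})

test_that("junction length statistics summarize counts, mean and population SD", {
  fake <- function(aa_len) {
    nt <- strrep("GCA", aa_len)
    structure(list(cdr3 = structure(list(nt_sequence = nt, aa_sequence =
      strrep("A", aa_len), in_frame = TRUE), class = "Cdr3"),
      junction_decomposition = NULL), class = "RearrangementRecord")
  }
  stats <- junction_length_stats(list(fake(5L), fake(43L)))
  aa <- stats$summary[stats$summary$quantity == "cdr3_aa_length", ]
  expect_equal(aa$mean, 24)
  expect_equal(aa$min, 5)
  expect_equal(aa$max, 43)
  expect_equal(aa$sd, 19)                  # population SD of {5, 43}

  empty <- junction_length_stats(list())
  expect_equal(empty$n, 0L)
  expect_true(all(is.na(empty$summary$mean)))
})

test_that("simulated trim histograms respect the configured support", {
  cfg <- sim_config(n_reads = 400, seed = 39, shm_rate = 0)
  sim <- simulate_repertoire(cfg)
  expect_lte(max(sim$truth$v_deletion), 8L)
  expect_equal(sort(unique(sim$truth$v_deletion))[1], 0L)
  expect_lte(max(sim$truth$j_deletion), 12L)
  ## mode at 0 for the configured heavy-chain table
  tb <- table(sim$truth$v_deletion)
  expect_equal(names(which.max(tb)), "0")
})
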