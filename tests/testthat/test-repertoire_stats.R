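fake_call <- function(id, clan = NA_character_, ties = id) {
  igjunction:::new_segment_call(structure(list(
    gene_id = id, read_interval = NULL, germline_interval = NULL,
    score = 0, percent_identity = 1, mutated_positions = NULL,
    map = NULL, core_offset = 0L), class = "SegmentAlignment"),
    ties, clan)
}

fake_record <- function(v = NULL, j = NULL, d = NULL, seq = "ACGT") {
  structure(list(read_id = "x", sequence = seq, v_call = v, j_call = j,
                 d_call = d, cdr3 = NULL, junction_decomposition = NULL),
            class = "RearrangementRecord")
}

test_that("usage percentages are exact fractions of assigned reads", {
  recs <- list(fake_record(fake_call("Vk18")), fake_record(fake_call("Vk18")),
               fake_record(fake_call("Vk9")), fake_record(fake_call("Vk11")))
  u <- usage_frequencies(recs, "V", "gene")
  expect_equal(u$label[1L], "Vk18")
  expect_equal(u$percent, c(50, 25, 25))
  expect_equal(sum(u$count), 4L)
  expect_equal(attr(u, "n_unassigned"), 0L)
  expect_equal(sum(u$percent), 100)
})

test_that("fully unassigned input yields an empty table with the unassigned count", {
  recs <- list(fake_record(), fake_record(), fake_record())
  u <- usage_frequencies(recs, "V", "gene")
  expect_equal(nrow(u), 0L)
  expect_equal(attr(u, "n_unassigned"), 3L)
})

test_that("gene-level usage aggregated by clan equals clan-level usage", {
  cfg <- sim_config(n_reads = 150, seed = 61, shm_rate = 0.02)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  gene_u <- usage_frequencies(recs, "V", "gene")
  clan_u <- usage_frequencies(recs, "V", "clan", cfg$germline_set)
  clan_of <- vapply(cfg$germline_set$genes[gene_u$label], function(g) g$clan,
                    character(1L))
  agg <- tapply(gene_u$count, clan_of, sum)
  expect_equal(sort(unname(unlist(agg))), sort(clan_u$count))
})

test_that("simulated segment-usage weights are recovered within multinomial error", {
  cfg <- sim_config(n_reads = 400, seed = 63, shm_rate = 0.02)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  u <- usage_frequencies(recs, "J", "gene")
  n <- attr(u, "n_assigned")
  for (jid in names(cfg$j_weights)) {
    p <- cfg$j_weights[[jid]]
    se <- sqrt(p * (1 - p) / n)
    got <- if (jid %in% u$label) u$count[u$label == jid] / n else 0
    expect_lt(abs(got - p), 3 * se + 1e-9, label = jid)
  }
})

test_that("combination-table marginals equal the per-segment usage tables", {
  cfg <- sim_config(n_reads = 120, seed = 65, shm_rate = 0.02)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  comb <- combination_table(recs, "gene")
  u_v <- usage_frequencies(recs, "V", "gene")
  u_j <- usage_frequencies(recs, "J", "gene")
  assigned <- Filter(function(r) !is.null(r$v_call) && !is.null(r$j_call), recs)
  expect_equal(sum(comb$count), length(assigned))
  v_marg <- tapply(comb$count, comb$v_label, sum)
  for (v in names(v_marg)) {
    expect_equal(unname(v_marg[[v]]), u_v$count[u_v$label == v])
  }
  j_marg <- tapply(comb$count, comb$j_label, sum)
  for (j in names(j_marg)) {
    expect_equal(unname(j_marg[[j]]), u_j$count[u_j$label == j])
  }
})

test_that("light-chain combination tables have V-J pairs only", {
  cfg <- sim_config(locus = "IGK", n_reads = 40, seed = 67, shm_rate = 0.02)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  comb <- combination_table(recs, "gene")
  expect_setequal(setdiff(colnames(comb), "count"), c("v_label", "j_label"))
})

test_that("segment contribution statistics report population mean and SD", {
  mk <- function(v_len, d = "IGHD1", d_len = 4L) {
    structure(list(
      cdr3 = structure(list(nt_sequence = strrep("A", 12L),
                            aa_sequence = "KKKK", in_frame = TRUE),
                       class = "Cdr3"),
      junction_decomposition = structure(list(
        retained_v_len = v_len, retained_j_len = 3L, d_gene = d,
        retained_d = strrep("G", d_len)), class = "JunctionDecomposition")),
      class = "RearrangementRecord")
  }
  out <- segment_contribution_stats(list(mk(4L), mk(6L)))
  v_row <- out[out$quantity == "retained_v", ]
  expect_equal(v_row$mean, 5)
  expect_equal(v_row$sd, 1)

  ## degenerate distribution: SD 0
  same <- segment_contribution_stats(list(mk(5L), mk(5L), mk(5L)))
  expect_equal(same[same$quantity == "retained_v", "sd"], 0)

  ## records without a D are excluded from the D statistic and counted
  no_d <- structure(list(
    cdr3 = structure(list(nt_sequence = "AAA", aa_sequence = "K",
                          in_frame = TRUE), class = "Cdr3"),
    junction_decomposition = structure(list(
      retained_v_len = 1L, retained_j_len = 1L, d_gene = NA_character_,
      retained_d = ""), class = "JunctionDecomposition")),
    class = "RearrangementRecord")
  out2 <- segment_contribution_stats(list(mk(4L), no_d))
  expect_equal(out2[out2$quantity == "retained_d", "n"], 1L)
  expect_equal(attr(out2, "n_no_d"), 1L)
})

test_that("CDR3 length equals the sum of its decomposition parts per record", {
  cfg <- sim_config(n_reads = 80, seed = 69)
  sim <- simulate_repertoire(cfg)
  recs <- annotate_reads(sim$reads, cfg$germline_set)
  checked <- 0L
  for (r in recs) {
    if (is.null(r$cdr3) || is.null(r$junction_decomposition)) next
    dec <- r$junction_decomposition
    if (is.na(dec$retained_j_len)) next
    parts <- dec$retained_v_len + nchar(dec$p1) + nchar(dec$n1) +
      nchar(dec$p_d5) + nchar(dec$retained_d) + nchar(dec$p_d3) +
      nchar(dec$n2) + nchar(dec$p2) + dec$retained_j_len
    expect_equal(nchar(r$cdr3$nt_sequence), parts, info = r$read_id)
    checked <- checked + 1L
  }
  expect_gt(checked, 50L)
})

test_that("deduplication collapses repeated reads only when requested", {
  r <- fake_record(fake_call("V1"), seq = "AAAA")
  recs <- list(r, r, fake_record(fake_call("V2"), seq = "CCCC"))
  u <- usage_frequencies(recs, "V", "gene")
  expect_equal(sum(u$count), 3L)
  u2 <- usage_frequencies(recs, "V", "gene", dedup = TRUE)
  expect_equal(sum(u2$count), 2L)
})
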