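test_that("germline FASTA loading attaches region bounds and validates input", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "germ.fasta")
  rg <- file.path(dir, "regions.tsv")
  write_germline(toy_igh, fa, rg)
  set <- load_germline(fa, rg)
  expect_setequal(names(set$genes), names(toy_igh$genes))
  expect_equal(set$genes$IGHV1$region_bounds$FR3, toy_igh$genes$IGHV1$region_bounds$FR3)
  expect_equal(set$genes$IGHV1$nt_sequence, toy_igh$genes$IGHV1$nt_sequence)

  writeLines(character(0L), fa)
  expect_error(load_germline(fa), "no records")

  writeLines(c(">IGHV1 IGH V", "ACGT", ">IGHV1 IGH V", "ACGT"), fa)
  expect_error(load_germline(fa), "IGHV1")

  expect_error(germline_gene("bad", "IGH", "V", "ACGQ"), "non-DNA")
})

test_that("the set locus is inferred from the loaded genes", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "k.fasta")
  rg <- file.path(dir, "k_regions.tsv")
  write_germline(toy_igk, fa, rg)
  set <- load_germline(fa, rg)
  expect_equal(set$locus, "IGK")
})

test_that("region table referencing unknown genes is rejected", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  rg <- file.path(dir, "r.tsv")
  writeLines(c(">IGHV1 IGH V", "ACGTACGT"), fa)
  writeLines(c("gene_id\tregion\tstart\tend", "IGHV9\tFR1\t0\t6"), rg)
  expect_error(load_germline(fa, rg), "IGHV9")
})

test_that("planted canonical RSS motifs are found at exact positions", {
  set.seed(11)
  seq <- paste0(random_seq(10), "CACAGTG", random_seq(23), "ACAAAAACC",
                random_seq(10))
  hits <- find_rss(seq, 23, max_heptamer_mm = 0, max_nonamer_mm = 0,
                   spacer_tolerance = 0, strands = "+")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 10L)
  expect_equal(hits$strand, "+")
  expect_equal(c(hits$heptamer_mm, hits$nonamer_mm), c(0L, 0L))

  expect_equal(nrow(find_rss("ACGT", 12)), 0L)
})

test_that("RSS scan equals the naive sliding-window oracle on seeded sequences", {
  set.seed(23)
  for (rep in 1:6) {
    spacer <- sample(c(12L, 23L), 1L)
    seq <- random_seq(800)
    ## plant 3 motifs, each with one heptamer mismatch outside CAC
    for (k in 1:3) {
      pos <- 50 + (k - 1) * 250
      hep <- "CACAGTG"
      i <- sample(4:7, 1L)
      substr(hep, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(hep, i, i)), 1L)
      motif <- paste0(hep, random_seq(spacer), "ACAAAAACC")
      substr(seq, pos, pos + nchar(motif) - 1L) <- motif
    }
    got <- find_rss(seq, spacer, max_heptamer_mm = 1, max_nonamer_mm = 2,
                    spacer_tolerance = 1)
    want <- naive_rss_scan(seq, spacer)
    expect_equal(got[, c("position", "strand", "spacer_length")], want,
                 ignore_attr = TRUE)
    expect_gte(nrow(got), 3L)
  }
})

test_that("minus-strand RSS hits mirror plus-strand hits of the reverse complement", {
  set.seed(31)
  seq <- paste0(random_seq(20), "CACAGTG", random_seq(12), "ACAAAAACC",
                random_seq(20))
  rc <- igjunction:::revcomp(seq)
  minus <- find_rss(rc, 12, strands = "-")
  plus <- find_rss(seq, 12, strands = "+")
  expect_equal(nrow(minus), nrow(plus))
  ## mirrored coordinate of a heptamer start
  expect_setequal(nchar(seq) - minus$position - 7L, plus$position)
})

test_that("V functionality classification follows the IMGT-style rules", {
  v1 <- toy_igh$genes$IGHV1
  expect_equal(classify_v_gene(v1)$functionality, "functional")

  ## second-Cys codon TGT -> AGT (Ser): intact ORF but ORF class
  orf <- v1
  substr(orf$nt_sequence, 289L, 289L) <- "A"
  expect_equal(classify_v_gene(orf)$functionality, "ORF")
  expect_equal(toy_igh$genes$IGHV7$functionality, "ORF")

  ## internal stop mid-FR2
  pse <- v1
  substr(pse$nt_sequence, 121L, 123L) <- "TAA"
  expect_equal(classify_v_gene(pse)$functionality, "pseudogene")
  expect_equal(toy_igh$genes$IGHV8$functionality, "pseudogene")

  ## no region bounds and nothing to infer from
  bare <- germline_gene("VX", "IGH", "V", v1$nt_sequence)
  res <- classify_v_gene(bare)
  expect_equal(res$functionality, "incomplete")
  expect_equal(res$reason, "unalignable")

  ## missing initiation codon in an annotated leader
  lead <- germline_gene("VL", "IGH", "V",
                        paste0("CTGGTG", v1$nt_sequence),
                        region_bounds = c(list(leader = c(0L, 6L)),
                                          lapply(igjunction:::TOY_V_BOUNDS,
                                                 function(b) b + 6L)))
  expect_equal(classify_v_gene(lead)$functionality, "ORF")
})

test_that("defect injection is monotone: a stop always demotes to pseudogene", {
  set.seed(5)
  for (i in 1:5) {
    v <- toy_igh$genes[[sprintf("IGHV%d", i)]]
    expect_equal(classify_v_gene(v)$functionality, "functional")
    codon_start <- sample(seq(103L, 180L, by = 3L), 1L)  # inside FR2/CDR2
    broken <- v
    substr(broken$nt_sequence, codon_start, codon_start + 2L) <- "TGA"
    expect_equal(classify_v_gene(broken)$functionality, "pseudogene")
  }
})

test_that("J classification requires WGXG (IGH) / FGXG (light) in an open frame", {
  j_ok <- germline_gene("J1", "IGH", "J", "ACGTACTGGGGCCAAGGGACC")
  res <- classify_j_gene(j_ok)
  expect_equal(res$functionality, "functional")

  expect_equal(classify_j_gene(toy_igh$genes$IGHJ3)$functionality, "pseudogene")
  expect_true(classify_j_gene(toy_igh$genes$IGHJ1)$tvss)

  ## X is any residue: F G S G works for kappa
  j_k <- germline_gene("JK", "IGK", "J", "TTTGGCTCAGGGACC")
  expect_equal(classify_j_gene(j_k)$functionality, "functional")

  j_bad <- germline_gene("JB", "IGH", "J", "ACGTACTCAGGACAAGCGACC")
  expect_equal(classify_j_gene(j_bad)$functionality, "pseudogene")
})

test_that("D open reading frames equal direct three-frame translation", {
  frames_by_translation <- function(seq) {
    which(vapply(0:2, function(f) {
      aa <- igjunction:::translate_frame(seq, f)
      !grepl("*", aa, fixed = TRUE)
    }, logical(1L))) - 1L
  }
  for (seq in c("GGTAGTGGT", "TAATAATAA", "GGCGGC", "TATGGTTATGGT")) {
    d <- germline_gene("D", "IGH", "D", seq)
    expect_equal(d_open_frames(d), frames_by_translation(seq), info = seq)
  }
  ## stop-rich: frame 0 is closed
  expect_false(0L %in% d_open_frames(germline_gene("D", "IGH", "D", "TAATAATAA")))
  ## no stop possible
  expect_equal(d_open_frames(germline_gene("D", "IGH", "D", "GGCGGC")), c(0L, 1L, 2L))
})

test_that("clan assignment matches a brute-force connected-components oracle", {
  triplet <- lapply(c("VA", "VB", "VC"), function(id) {
    g <- toy_igh$genes$IGHV1; g$gene_id <- id; g
  })
  expect_equal(unname(assign_clans(triplet)$clans), rep("I", 3L))

  ## two dissimilar genes split
  set.seed(7)
  g1 <- toy_igh$genes$IGHV1
  g2 <- germline_gene("IGHVX", "IGH", "V",
                      paste0(igjunction:::random_orf(291L), random_seq(10)),
                      region_bounds = igjunction:::TOY_V_BOUNDS)
  expect_equal(length(unique(assign_clans(list(g1, g2))$clans)), 2L)

  ## 12 synthetic genes from 3 seeds, <=5% mutations each
  set.seed(13)
  seeds <- replicate(3, igjunction:::toy_core_seed())
  genes <- list()
  for (s in 1:3) for (m in 1:4) {
    core <- if (m == 1) seeds[s] else igjunction:::mutate_core(seeds[s], 12L)
    genes[[length(genes) + 1L]] <-
      germline_gene(sprintf("V%d_%d", s, m), "IGH", "V",
                    paste0(core, random_seq(10)),
                    region_bounds = igjunction:::TOY_V_BOUNDS)
  }
  res <- assign_clans(genes, identity_threshold = 0.75)
  ## oracle: exhaustive pairwise identity + connected components
  n <- length(genes)
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    adj[i, j] <- pairwise_identity(igjunction:::v_core_seq(genes[[i]]),
                                   igjunction:::v_core_seq(genes[[j]])) >= 0.75
  }
  comp <- rep(0L, n); cur <- 0L
  for (i in 1:n) if (comp[i] == 0L) {
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      k <- stack[1L]; stack <- stack[-1L]
      if (comp[k] == 0L) { comp[k] <- cur; stack <- c(stack, which(adj[k, ])) }
    }
  }
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  expect_equal(length(unique(res$clans)), length(unique(comp)))
  oracle_part <- split(ids, comp)
  got_part <- split(names(res$clans), res$clans)
  expect_setequal(unname(lapply(oracle_part, sort)),
                  unname(lapply(got_part, sort)))
})

test_that("clan labelling is invariant to input order", {
  vs <- igjunction:::genes_of_type(toy_igh, "V")
  vs <- Filter(function(g) g$functionality == "functional", vs)
  a <- assign_clans(vs)$clans
  b <- assign_clans(rev(vs))$clans
  expect_identical(a[sort(names(a))], b[sort(names(b))])
  expect_equal(length(unique(a)), 2L)
})
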