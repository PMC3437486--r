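test_that("planted perfect repeats are detected exactly", {
  s <- paste0("CCTTC", strrep("AG", 8), "TTCCG")
  m <- find_ssrs(s, tus_id = "t1")
  expect_equal(nrow(m), 1L)
  expect_equal(m$unit, "AG")
  expect_equal(m$repeat_count, 8L)
  expect_equal(m$total_length, 16L)
  expect_equal(m$start, 6L)

  m2 <- find_ssrs(paste0("CCG", strrep("TTC", 7), "GGA"))
  expect_equal(m2$unit, "TTC")
  expect_equal(m2$total_length, 21L)
  # uniqueness confirmed by the brute-force enumeration oracle
  expect_equal(m2[-1], oracle_find_ssrs(paste0("CCG", strrep("TTC", 7),
                                               "GGA"))[-1])

  expect_equal(nrow(find_ssrs(strrep("A", 9))), 0L)  # below mono threshold
  expect_equal(find_ssrs(strrep("A", 10))$repeat_count, 10L)
})

test_that("a repeat tract is reported once, at its shortest period", {
  m <- find_ssrs(paste0("CCG", strrep("AT", 12), "GCC"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$unit, "AT")
  expect_equal(m$repeat_count, 12L)
})

test_that("units are reported non-canonically but group canonically on request", {
  expect_equal(find_ssrs(paste0("CC", strrep("GA", 7), "TT"))$unit, "GA")
  expect_equal(canonical_unit(c("AG", "GA", "TC", "CT")),
               rep("AG", 4))
})

test_that("detector agrees with the brute-force oracle on short sequences", {
  set.seed(101)
  relaxed <- c(6L, 3L, 3L, 3L, 3L, 3L)
  for (i in 1:120) {
    alpha <- if (i %% 3 == 0) c("A", "T") else
      if (i %% 3 == 1) c("A", "C", "G", "T") else c("A", "G", "C")
    s <- rand_dna(sample(20:200, 1), alphabet = alpha)
    mr <- if (i %% 2 == 0) misa_min_repeats() else relaxed
    got <- find_ssrs(s, min_repeats = mr)
    want <- oracle_find_ssrs(s, min_repeats = mr)
    expect_equal(got, want, info = paste("seq:", s))
  }
})

test_that("planted repeats in simulated transcriptomes are fully recalled", {
  cfg <- sim_config(seed = 33, n_tus = 120L)
  sim <- simulate_transcriptome(cfg)
  motifs <- find_ssrs_set(sim$tus)
  truth <- sim$truth$ssrs
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    any(motifs$tus_id == truth$tus_id[i] &
          motifs$unit == truth$unit[i] &
          motifs$start <= truth$start[i] &
          motifs$end >= truth$start[i] +
            nchar(truth$unit[i]) * truth$repeat_count[i] - 1L)
  }, NA)
  expect_true(all(recalled))
})

test_that("compound flagging groups motifs within the interruption limit", {
  motifs <- rbind(
    find_ssrs(paste0("CCTTC", strrep("AG", 8), "GGAAG", strrep("TC", 6),
                     "GGAAC"), tus_id = "x"))
  m <- merge_compound(motifs, max_interruption = 100L)
  expect_true(all(m$compound))
  expect_equal(unique(m$compound_id), 1L)

  far <- data.frame(tus_id = "y", start = c(1L, 200L), end = c(16L, 215L),
                    unit = c("AG", "TC"), unit_len = 2L, repeat_count = 8L,
                    total_length = 16L, stringsAsFactors = FALSE)
  expect_false(any(merge_compound(far, 100L)$compound))

  chain <- data.frame(tus_id = "z", start = c(1L, 37L, 73L),
                      end = c(26L, 62L, 98L), unit = "AG", unit_len = 2L,
                      repeat_count = 13L, total_length = 26L,
                      stringsAsFactors = FALSE)
  mc <- merge_compound(chain, 10L)
  expect_true(all(mc$compound))
  expect_equal(length(unique(mc$compound_id)), 1L)
  # transitive-closure oracle agrees
  expect_equal(oracle_transitive_groups(chain$start, chain$end, 10L),
               rep(1L, 3))
})

test_that("Class I selection uses the 20-nt tract boundary inclusively", {
  expect_equal(classify_ssr(c(21L, 16L, 20L, 19L)), c("I", "II", "I", "II"))
})

test_that("marker-candidate filtering excludes mono motifs and short products", {
  motifs <- data.frame(unit_len = c(1L, 2L, 3L, 2L))
  design <- data.frame(success = c(TRUE, TRUE, TRUE, FALSE),
                       product_size = c(200L, 95L, 180L, NA))
  expect_equal(filter_marker_candidates(motifs, design),
               c(FALSE, FALSE, TRUE, FALSE))
})

test_that("redundancy screen drops only candidates matched on all three thresholds", {
  cands <- c("q1", "q2", "q3")
  qlens <- c(q1 = 200L, q2 = 200L, q3 = 200L)
  hits <- data.frame(
    query = c("q1", "q2"), subject = "prior",
    pct_identity = c(95, 95), aln_len = c(100, 40), mismatches = 0,
    gap_opens = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 1e-20, bitscore = 180, stringsAsFactors = FALSE)
  # q1: qcov 50% >= 30, id 95 > 90, E <= 1e-5 -> dropped; q2: qcov 20% -> kept
  expect_equal(redundancy_screen(cands, hits, qlens), c("q2", "q3"))
  expect_equal(redundancy_screen(cands, hits[0, ], qlens), cands)
  hits$query[1] <- "unknown"
  expect_error(redundancy_screen(cands, hits, qlens), "unknown candidate")
})

test_that("PIC follows the Botstein closed form", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(-0.5, 1.5)), "nonnegative")
})

test_that("search summaries mirror the truth table and conserve counts", {
  cfg <- sim_config(seed = 5, n_tus = 100L,
                    ssr_plants = data.frame(
                      unit = c("AG", "TTC"), repeat_count = c(8L, 7L),
                      count = c(20L, 17L), stringsAsFactors = FALSE),
                    polya_fraction = 0)
  sim <- simulate_transcriptome(cfg)
  motifs <- merge_compound(find_ssrs_set(sim$tus))
  s <- summarize_search(sim$tus, motifs)
  expect_equal(s$n_sequences, 100L)
  expect_equal(s$total_bp, sum(nchar(sim$tus$seq)))
  expect_equal(sum(unlist(s[paste0("n_unit", 1:6)])), s$n_ssrs)
  expect_lte(s$n_sequences_with_ssr, s$n_sequences)
  expect_lte(s$n_compound, s$n_ssrs)
  # every planted motif is in the count
  expect_gte(s$n_ssrs, nrow(sim$truth$ssrs))

  s0 <- summarize_search(sim$tus, motifs[0, ])
  expect_equal(s0$n_ssrs, 0L)
  expect_equal(s0$n_sequences, 100L)
})

test_that("MISA-style output table carries one row per motif", {
  s <- paste0("CCTTC", strrep("AG", 8), "GGAAG", strrep("TC", 6), "GGAAC")
  motifs <- merge_compound(find_ssrs(s, tus_id = "t1"))
  f <- withr::local_tempfile()
  write_misa(motifs, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$SSR, c("(AG)8", "(TC)6"))
  expect_true(all(grepl("^c\\*p2$", tab$SSR_type)))
})
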