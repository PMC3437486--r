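test_that("the index holds every k-mer and skips short TUSs", {
  tus <- seq_set("one", rand_dna(100))
  idx <- build_tag_index(tus, 36L)
  expect_equal(sum(idx$pos_strand == "+"), 65L)  # 100 - 36 + 1
  expect_equal(sum(idx$pos_strand == "-"), 65L)

  short <- seq_set(c("a", "b"), c(rand_dna(20), rand_dna(60)))
  expect_warning(idx2 <- build_tag_index(short, 36L), "skipped")
  expect_false("a" %in% short$id[idx2$pos_tus])
})

test_that("tags map to all equal-best placements", {
  set.seed(3)
  s1 <- rand_dna(120)
  s2 <- rand_dna(120)
  shared <- rand_dna(36)
  tus <- seq_set(c("t1", "t2", "t3"),
                 c(paste0(s1, shared), paste0(shared, s2), rand_dna(80)))
  idx <- build_tag_index(tus, 36L)

  unique_tag <- substr(s1, 10L, 45L)
  a <- map_tags(unique_tag, idx)
  expect_equal(nrow(a), 1L)
  expect_equal(a$tus_id, "t1")
  expect_equal(a$pos, 10L)
  expect_equal(a$n_equal_best, 1L)
  expect_equal(a$mismatches, 0L)

  a2 <- map_tags(shared, idx)
  expect_equal(unique(a2$n_equal_best), 2L)
  expect_setequal(a2$tus_id, c("t1", "t2"))

  # reverse-complement tags map on the minus strand at the right coords
  a3 <- map_tags(revcomp(unique_tag), idx)
  expect_equal(a3$strand, "-")
  expect_equal(a3$pos, 10L)

  # one mismatch is found by the pigeonhole seeds, two are not
  mut1 <- unique_tag
  substr(mut1, 18L, 18L) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mut1, 18, 18))[1]
  a4 <- map_tags(mut1, idx)
  expect_equal(a4$mismatches, 1L)
  expect_equal(a4$pos, 10L)
  mut2 <- mut1
  substr(mut2, 30L, 30L) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mut2, 30, 30))[1]
  expect_equal(nrow(map_tags(mut2, idx)), 0L)
  expect_equal(nrow(map_tags(mut2, idx, max_mismatches = 0L)), 0L)
})

test_that("the mapper agrees with a brute-force all-positions scan", {
  set.seed(17)
  tus <- make_tus(10L, 150L, seed = 17)
  idx <- build_tag_index(tus, 36L)
  for (r in 1:40) {
    i <- sample(10L, 1)
    p <- sample(150L - 35L, 1)
    tag <- substr(tus$seq[i], p, p + 35L)
    if (r %% 2 == 0) {
      q <- sample(36L, 1)
      substr(tag, q, q) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (r %% 5 == 0) tag <- revcomp(tag)
    got <- map_tags(tag, idx)
    want <- oracle_map_tag(tag, tus)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      key <- function(d) sort(paste(d$tus_id, d$pos, d$strand, d$mismatches))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("counting policies behave and fractional counts conserve mass", {
  aln <- data.frame(tag = c(1:10, 11, 11),
                    tus_id = c(rep("t1", 10), "t1", "t2"),
                    pos = 1L, strand = "+", mismatches = 0L,
                    n_equal_best = c(rep(1L, 10), 2L, 2L),
                    stringsAsFactors = FALSE)
  expect_equal(count_tags(aln, "unique_only")$count, c(10, 0))
  expect_equal(count_tags(aln, "all")$count, c(11, 1))
  frac <- count_tags(aln, "fractional")
  expect_equal(frac$count, c(10.5, 0.5))
  expect_equal(sum(frac$count), 11)  # = number of mapped tags
})

test_that("the R-statistic matches its closed form and is symmetric", {
  expect_equal(r_statistic(10, 10, 1e6, 1e6), 0)
  expect_equal(r_statistic(20, 0, 1e6, 1e6), 20 * log(2))
  expect_equal(r_statistic(100, 25, 1e6, 1e6),
               100 * log(1.6) + 25 * log(0.4))
  expect_error(r_statistic(0, 0, 1e6, 1e6), "both counts")

  set.seed(9)
  for (i in 1:50) {
    x1 <- rpois(1, 20); x2 <- rpois(1, 5)
    if (x1 + x2 == 0) next
    N1 <- 1e6; N2 <- 2e6
    expect_equal(r_statistic(x1, x2, N1, N2), r_statistic(x2, x1, N2, N1))
    expect_gte(r_statistic(x1, x2, N1, N2), 0)
  }
})

test_that("expression categories partition the TUS set", {
  expect_equal(classify_expression(5, 3), "both")
  expect_equal(classify_expression(4, 0), "exclusive_g1")
  expect_equal(classify_expression(0, 7), "exclusive_g2")
  expect_equal(classify_expression(0, 0), "undetected")
  set.seed(2)
  x1 <- rpois(500, 0.7); x2 <- rpois(500, 0.7)
  cat4 <- table(factor(classify_expression(x1, x2),
                       levels = c("both", "exclusive_g1", "exclusive_g2",
                                  "undetected")))
  expect_equal(sum(cat4), 500L)
})

test_that("fold bins split |log2fc| at the documented boundaries", {
  expect_equal(fold_bin(c(0, 0.99, 1, 2.5, 3, 4, 4.3, -4.5, -2.5)),
               c("lt1", "lt1", "b1_2", "b2_3", "b3_4", "b3_4", "gt4",
                 "gt4", "b2_3"))
})

test_that("the expression table enforces its field invariants", {
  c1 <- data.frame(tus_id = c("a", "b", "c", "d"), count = c(100, 0, 7, 0))
  c2 <- data.frame(tus_id = c("a", "b", "c", "d"), count = c(25, 5, 0, 0))
  tbl <- expression_table(c1, c2, N1 = 1e5, N2 = 2e5)
  expect_equal(tbl$cpm1, c1$count * 1e6 / 1e5)
  expect_equal(tbl$cpm2, c2$count * 1e6 / 2e5)
  expect_equal(is.na(tbl$log2fc), tbl$category != "both")
  expect_equal(tbl$fold_bin == "undefined", tbl$category != "both")
  expect_true(is.na(tbl$R[tbl$category == "undetected"]))
  expect_equal(tbl$log2fc[1], log2((100 / 1e5) / (25 / 2e5)))
})

test_that("DE selection matches the inclusion-exclusion oracle", {
  # constructed counts: A-only rows pass the fold criterion with small R,
  # B-only rows pass R with |log2fc| < 2, two rows pass both
  mk <- function(x1, x2, n, tag) {
    data.frame(tus_id = sprintf("%s%03d", tag, seq_len(n)),
               x1 = x1, x2 = x2, stringsAsFactors = FALSE)
  }
  rows <- rbind(mk(4, 1, 30, "A"), mk(300, 150, 10, "B"),
                mk(40, 1, 2, "AB"), mk(50, 50, 58, "N"))
  c1 <- data.frame(tus_id = rows$tus_id, count = rows$x1)
  c2 <- data.frame(tus_id = rows$tus_id, count = rows$x2)
  tbl <- expression_table(c1, c2, N1 = 1e6, N2 = 1e6)
  de <- select_de_set(tbl)
  expect_equal(de$n_fold, 32L)      # A-only + both
  expect_equal(de$n_r, 12L)         # B-only + both
  expect_equal(de$n_overlap, 2L)
  expect_equal(de$n_union, de$n_fold + de$n_r - de$n_overlap)
  expect_setequal(de$de, tbl$tus_id[grepl("^A|^B", tbl$tus_id)])

  empty <- expression_table(c1[0, ], c2[0, ], N1 = 1, N2 = 1)
  expect_equal(select_de_set(empty)$n_union, 0L)
  expect_equal(de_union_size(2860, 116, 2), 2974)
})
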