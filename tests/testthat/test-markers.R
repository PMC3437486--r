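blocks2 <- function(gaps, exon = 100L, score = 1000) {
  # consecutive exons of fixed length separated by the given genomic gaps
  n <- length(gaps) + 1L
  gstart <- integer(n); gend <- integer(n)
  gstart[1] <- 1L; gend[1] <- exon
  for (i in seq_along(gaps)) {
    gstart[i + 1L] <- gend[i] + gaps[i] + 1L
    gend[i + 1L] <- gstart[i + 1L] + exon - 1L
  }
  data.frame(aln_id = "a1", tus_id = "t1", genome_seq_id = "chr1",
             strand = "+", gstart = gstart, gend = gend,
             tstart = seq.int(1L, by = exon, length.out = n),
             tend = seq.int(exon, by = exon, length.out = n),
             score = score, stringsAsFactors = FALSE)
}

test_that("introns are inferred from genomic gaps within the size limits", {
  b <- blocks2(100L)
  intr <- infer_introns(b)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$donor, 101L)
  expect_equal(intr$acceptor, 200L)
  expect_equal(intr$length, 100L)
  expect_equal(intr$junction, 100L)

  expect_equal(nrow(infer_introns(blocks2(6000L))), 0L)  # above the cap
  expect_equal(nrow(infer_introns(blocks2(15L))), 0L)    # below the floor
  mixed <- infer_introns(blocks2(c(500L, 15L, 800L)))
  expect_equal(mixed$length, c(500L, 800L))
})

test_that("transcribed units merge across gaps of at most 1000 bp", {
  spans <- data.frame(aln_id = c("a", "b"), gstart = c(1L, 1301L),
                      gend = c(500L, 1800L), stringsAsFactors = FALSE)
  expect_equal(merge_transcribed_units(spans)$unit, c(1L, 1L))  # gap 800
  spans$gstart[2] <- 1701L  # gap 1200
  expect_equal(merge_transcribed_units(spans)$unit, c(1L, 2L))

  chain <- data.frame(aln_id = c("a", "b", "c"),
                      gstart = c(1L, 1401L, 2801L),
                      gend = c(500L, 1900L, 3300L), stringsAsFactors = FALSE)
  m <- merge_transcribed_units(chain)
  expect_equal(m$unit, rep(1L, 3))
  expect_equal(oracle_transitive_groups(chain$gstart, chain$gend, 1000L),
               rep(1L, 3))
  # order invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    m2 <- merge_transcribed_units(chain[perm, ])
    grp <- split(m2$aln_id, m2$unit)
    expect_equal(lapply(grp, sort), lapply(split(m$aln_id, m$unit), sort))
  }
})

test_that("ISR pairs sit in flanking exons and obey the genomic-product identity", {
  set.seed(77)
  tus_seq <- rand_dna(400)
  b <- blocks2(350L, exon = 200L)
  intr <- infer_introns(b)
  pairs <- design_isr(tus_seq, b, intr)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$product_size_genomic,
               pairs$product_size_transcript + 350L)
  # left primer inside exon 1, right inside exon 2 (transcript coords)
  expect_lte(pairs$left_pos + nchar(pairs$left_seq) - 1L, 200L)
  expect_gte(pairs$right_pos - nchar(pairs$right_seq) + 1L, 201L)
  # product spans the junction
  expect_lte(pairs$left_pos, 200L)
  expect_gte(pairs$right_pos, 201L)
})

test_that("the GSS-style hit filter applies only the supplied thresholds", {
  hit <- function(aln_len, id, ev) {
    data.frame(query = "q1", subject = "g1", pct_identity = id,
               aln_len = aln_len, mismatches = 0, gap_opens = 0,
               qstart = 1, qend = aln_len, sstart = 1, send = aln_len,
               evalue = ev, bitscore = 100, stringsAsFactors = FALSE)
  }
  gss <- function(h) filter_hits_cascade(h, evalue_max = 1e-10,
                                         min_identity_pct = 80,
                                         min_qaln_len = 70)
  expect_equal(gss(hit(100, 85, 1e-12))$n_queries, 1L)
  expect_equal(gss(hit(60, 85, 1e-12))$n_queries, 0L)
  expect_equal(gss(hit(100, 85, 1e-8))$n_queries, 0L)
  expect_equal(gss(hit(100, 79, 1e-12))$n_queries, 0L)
  expect_equal(gss(hit(100, 85, 1e-12)[0, ])$n_queries, 0L)
  # coverage filtering needs query lengths
  expect_error(filter_hits_cascade(hit(100, 85, 1e-12), evalue_max = 1,
                                   min_qcov_pct = 30),
               "query lengths")
})

test_that("the COS cascade reproduces designed stage outcomes", {
  orth <- simulate_ortholog_hits(seed = 12, n_families = 50L,
                                 n_fail_stage1 = 10L, n_fail_stage2 = 10L,
                                 n_paralog = 5L, n_prior_cos = 5L)
  cas <- cos_cascade(orth$species_hits, orth$annotations,
                     orth$prior_cos_hits, orth$qlens)
  expect_equal(cas$stages, orth$truth$stages)
  expect_true(all(diff(cas$stages) <= 0))  # monotone
  # a family present in only 5/6 species fails stage 1
  expect_false("Q001" %in% cas$stage1)
  # a planted within-species duplicate is flagged paralogous
  paralogs <- names(orth$truth$groups)[orth$truth$groups == "paralog"]
  expect_true(all(paralogs %in% cas$stage2))
  expect_false(any(paralogs %in% cas$stage3))

  expect_error(cos_cascade(orth$species_hits[1:5], orth$annotations,
                           orth$prior_cos_hits, orth$qlens),
               "six species")
})

test_that("annotation normalization ignores case, punctuation and suffixes", {
  expect_equal(normalize_annotation("Heat-Shock Protein 70, isoform X2"),
               normalize_annotation("heat shock protein 70"))
  expect_false(normalize_annotation("protein kinase") ==
                 normalize_annotation("phosphatase"))
})

test_that("GFF3 alignments round-trip and score filtering keeps near-best", {
  set.seed(55)
  cfg <- sim_config(seed = 55, n_tus = 40L, n_genes_with_introns = 5L,
                    n_close_pairs = 2L)
  sim <- simulate_transcriptome(cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  gen <- simulate_genome_and_alignments(cfg, sim$tus, f)
  blocks <- read_spliced_alignments(f)
  cols <- c("aln_id", "tus_id", "gstart", "gend", "tstart", "tend")
  got <- blocks[do.call(order, blocks[cols]), cols]
  want <- gen$blocks[do.call(order, gen$blocks[cols]), cols]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  # intron truth equals gaps recomputed from the GFF3 blocks
  for (aln in split(blocks, blocks$aln_id)) {
    intr <- infer_introns(aln[order(aln$gstart), ])
    truth <- gen$truth$introns[gen$truth$introns$tus_id == aln$tus_id[1], ]
    expect_equal(intr$length, truth$length)
    expect_equal(intr$junction, truth$junction)
  }

  # low-scoring secondary alignments are dropped before ISR design
  low <- blocks[1, ]
  low$aln_id <- "aln_low"
  low$score <- 100
  kept <- filter_alignment_score(rbind(blocks, low))
  expect_false("aln_low" %in% kept$aln_id)
  expect_setequal(unique(kept$aln_id), unique(blocks$aln_id))
})
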