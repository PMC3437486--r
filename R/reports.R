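# Report tables and end-to-end pipeline orchestration.
#
# Row and column labels mirror the conventional SSR-search summary and
# the SNP frequency-by-depth classification matrix; totals rows are
# always computed from the component rows, never copied.

SSR_SUMMARY_LABELS <- c(
  n_sequences = "Total number of TUSs examined",
  total_bp = "Total size of examined sequences (bp)",
  n_ssrs = "Total number of identified SSRs",
  n_sequences_with_ssr = "Number of SSR containing sequences",
  n_sequences_with_multiple = "Number of sequences containing >1 SSR",
  n_compound = "Number of SSRs present in compound formation",
  n_unit1 = "Mono-nucleotide repeats",
  n_unit2 = "Di-nucleotide repeats",
  n_unit3 = "Tri-nucleotide repeats",
  n_unit4 = "Tetra-nucleotide repeats",
  n_unit5 = "Penta-nucleotide repeats",
  n_unit6 = "Hexa-nucleotide repeats")

#' Write the SSR search summary as a labelled two-column TSV
#'
#' The "Total number of identified SSRs" row is recomputed as the sum of
#' the six per-unit-length rows.
#'
#' @param summary one-row data.frame from [summarize_search()].
#' @param path output TSV.
#' @return the labelled data.frame, invisibly.
#' @export
report_ssr_summary <- function(summary, path = NULL) {
  vals <- unlist(summary[1, names(SSR_SUMMARY_LABELS)])
  vals["n_ssrs"] <- sum(vals[paste0("n_unit", 1:6)])
  df <- data.frame(label = unname(SSR_SUMMARY_LABELS), value = unname(vals),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(df)
}

#' Write the SNP classification matrix as a labelled TSV
#'
#' @param m 10 x 4 matrix from [classification_matrix()].
#' @param path output TSV.
#' @return the matrix with a computed totals row, invisibly.
#' @export
report_snp_matrix <- function(m, path = NULL) {
  out <- rbind(m, Total = colSums(m))
  if (!is.null(path)) {
    df <- data.frame(`Frequency difference range` = rownames(out),
                     out, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Differential-expression accounting report
#'
#' Emits the inclusion-exclusion accounting of the DE set: size of the
#' fold-change set, of the R-statistic set, of their overlap and of
#' their union.
#'
#' @param de list from [select_de_set()].
#' @param path optional JSON output file.
#' @return named list of the four counts, invisibly.
#' @export
report_de_accounting <- function(de, path = NULL) {
  acc <- list(n_fold = de$n_fold, n_r = de$n_r, n_overlap = de$n_overlap,
              n_union = de_union_size(de$n_fold, de$n_r, de$n_overlap))
  if (!is.null(path)) {
    jsonlite::write_json(acc, path, auto_unbox = TRUE)
  }
  invisible(acc)
}

#' COS cascade accounting report
#'
#' @param cascade list from [cos_cascade()].
#' @param path optional TSV output.
#' @return data.frame of per-stage counts, invisibly.
#' @export
report_cos_accounting <- function(cascade, path = NULL) {
  df <- data.frame(
    stage = c("six-species similarity", "identical annotation",
              "paralog removal", "prior-COS exclusion"),
    n = as.integer(cascade$stages))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}

#' Run the full toy pipeline on synthetic data
#'
#' Simulates a transcriptome, genome, two tag libraries and ortholog hit
#' tables under one seed, then runs every downstream stage: poly-A
#' trimming, SSR mining and summary, tag mapping and expression with DE
#' accounting, variant calling with the classification matrix and VCF,
#' ISR design, and the COS cascade. All outputs are written under
#' `out_dir`.
#'
#' @param cfg from [sim_config()]; its seed fixes all randomness.
#' @param out_dir output directory (created if needed).
#' @return invisible list with every intermediate result (`tus`,
#'   `ssr`, `expression`, `de`, `variants`, `isr`, `cos`, ...).
#' @export
run_toy_pipeline <- function(cfg = sim_config(), out_dir = tempfile("toy")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  sim <- simulate_transcriptome(cfg)
  tus <- sim$tus
  tus$seq <- trim_polya(tus$seq)
  keep <- screen_low_complexity(tus$seq) & nchar(tus$seq) >= 50L
  tus <- tus[keep, , drop = FALSE]
  write_fasta(tus, p("tus.fasta"))

  motifs <- find_ssrs_set(tus)
  motifs <- merge_compound(motifs)
  motifs$ssr_class <- classify_ssr(motifs$total_length)
  write_misa(motifs, p("ssr.tsv"))
  ssr_summary <- summarize_search(tus, motifs)
  report_ssr_summary(ssr_summary, p("ssr_summary.tsv"))

  gen <- simulate_genome_and_alignments(cfg, tus, p("alignments.gff3"))
  write_fasta(gen$genome, p("genome.fasta"))

  pv <- plant_variants(cfg, tus)
  tg <- simulate_tags(cfg, tus, pv$hap2)
  write_fastq(tg$tags1, p("tags_g1.fastq"))
  write_fastq(tg$tags2, p("tags_g2.fastq"))

  index <- suppressWarnings(build_tag_index(tus, cfg$tag_length))
  aln1 <- map_tags(tg$tags1$seq, index)
  aln2 <- map_tags(tg$tags2$seq, index)
  c1 <- count_tags(aln1, "unique_only", tus_ids = tus$id)
  c2 <- count_tags(aln2, "unique_only", tus_ids = tus$id)
  expr <- expression_table(c1, c2)
  utils::write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  de <- select_de_set(expr)
  report_de_accounting(de, p("de_accounting.json"))

  u1 <- aln1[aln1$n_equal_best == 1L, , drop = FALSE]
  u2 <- aln2[aln2$n_equal_best == 1L, , drop = FALSE]
  pile1 <- build_pileup(u1, tg$tags1$seq, tus)
  pile2 <- build_pileup(u2, tg$tags2$seq, tus)
  cand <- call_candidates(pile1, pile2, tus)
  m <- classification_matrix(cand)
  report_snp_matrix(m, p("snp_matrix.tsv"))
  passed <- cand[cand$pass_filter, , drop = FALSE]
  write_vcf(passed, tus, p("variants.vcf"))

  blocks <- read_spliced_alignments(p("alignments.gff3"))
  blocks <- filter_alignment_score(blocks)
  isr <- list()
  for (aln in split(blocks, blocks$aln_id)) {
    introns <- infer_introns(aln)
    if (nrow(introns) == 0L) next
    tus_seq <- tus$seq[match(aln$tus_id[1], tus$id)]
    pairs <- design_isr(tus_seq, aln, introns)
    if (nrow(pairs)) {
      pairs <- cbind(tus_id = aln$tus_id[1], pairs)
      isr[[length(isr) + 1L]] <- pairs
    }
  }
  isr <- if (length(isr)) do.call(rbind, isr) else NULL
  if (!is.null(isr)) {
    utils::write.table(isr, p("isr_primers.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  orth <- simulate_ortholog_hits(seed = cfg$seed + 4L)
  cos <- cos_cascade(orth$species_hits, orth$annotations,
                     orth$prior_cos_hits, orth$qlens)
  report_cos_accounting(cos, p("cos_accounting.tsv"))

  invisible(list(cfg = cfg, out_dir = out_dir, tus = tus, sim = sim,
                 motifs = motifs, ssr_summary = ssr_summary, genome = gen,
                 planted = pv, tags = tg, expr = expr, de = de,
                 pileup1 = pile1, pileup2 = pile2,
                 candidates = cand, snp_matrix = m, isr = isr,
                 ortholog = orth, cos = cos))
}
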