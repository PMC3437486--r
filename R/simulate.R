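# Seeded synthetic-data generator with machine-readable planted truth.
#
# Every simulate_* function seeds the RNG from the config, so identical
# configs give byte-identical outputs end to end. Desk-scale defaults
# (500 TUSs, 1e5 tags per library) keep every stage runnable in seconds
# while exercising all downstream rules.

#' Simulation configuration
#'
#' @param seed master seed; every source of randomness derives from it.
#' @param n_tus number of transcripts (default 500).
#' @param tus_len_min,tus_len_max,tus_len_mean transcript length
#'   distribution (truncated log-normal around the mean).
#' @param ssr_plants data.frame (`unit`, `repeat_count`, `count`) of
#'   repeats to plant; default plants (AG)8, (TTC)7 and (A)12 batches.
#' @param polya_fraction fraction of transcripts given a 3' poly-A tail
#'   (default 0.2, tail 12-25 nt).
#' @param n_genes_with_introns transcripts given intron structure on the
#'   toy genome (default 30).
#' @param intron_len_min,intron_len_max planted intron lengths (default
#'   80-2000, all within the 5000 cap).
#' @param n_close_pairs intronless transcript pairs placed <= 1000 bp
#'   apart on the genome to exercise transcribed-unit merging
#'   (default 5).
#' @param n_variants planted inter-genotype substitutions (default 60).
#' @param variant_freq designed alternate-allele frequency (default 1,
#'   homozygous difference).
#' @param abundance_meanlog,abundance_sdlog log-normal transcript
#'   abundance model (default meanlog 3, sdlog 1.2).
#' @param fold_changes data.frame (`log2fc`, `n_genes`) of planted fold
#'   changes (default 10 genes at +3 and 10 at -3).
#' @param N1,N2 library sizes in tags (default 1e5 each).
#' @param tag_length tag length (default 36).
#' @param error_rate per-base substitution error rate (default 0.01).
#' @return config list.
#' @export
sim_config <- function(seed = 1L, n_tus = 500L, tus_len_min = 150L,
                       tus_len_max = 1200L, tus_len_mean = 460,
                       ssr_plants = data.frame(
                         unit = c("AG", "TTC", "A"),
                         repeat_count = c(8L, 7L, 12L),
                         count = c(15L, 15L, 10L),
                         stringsAsFactors = FALSE),
                       polya_fraction = 0.2, n_genes_with_introns = 30L,
                       intron_len_min = 80L, intron_len_max = 2000L,
                       n_close_pairs = 5L, n_variants = 60L,
                       variant_freq = 1, abundance_meanlog = 3,
                       abundance_sdlog = 1.2,
                       fold_changes = data.frame(log2fc = c(3, -3),
                                                 n_genes = c(10L, 10L)),
                       N1 = 1e5L, N2 = 1e5L, tag_length = 36L,
                       error_rate = 0.01) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tus > 0, cfg$intron_len_max <= 5000L,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$variant_freq > 0, cfg$variant_freq <= 1)
  cfg
}

random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a TUS set with planted SSRs and poly-A tails
#'
#' Repeats are planted at recorded, well-separated positions inside
#' random-composition transcripts; a configured fraction of transcripts
#' additionally receives a 3' poly-A tail (recorded in truth, so trimming
#' can be checked).
#'
#' @param cfg from [sim_config()].
#' @return list: `tus` (sequence set), `truth` list with `ssrs`
#'   (data.frame `tus_id`, `start`, `unit`, `repeat_count`) and
#'   `polya` (data.frame `tus_id`, `tail_len`).
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  len <- round(exp(log(cfg$tus_len_mean) +
                     stats::rnorm(cfg$n_tus, 0, 0.35)))
  len <- pmin(pmax(len, cfg$tus_len_min), cfg$tus_len_max)
  seqs <- random_dna(len)
  ids <- sprintf("TUS%04d", seq_len(cfg$n_tus))
  # plant SSRs in distinct hosts, away from the ends
  plants <- cfg$ssr_plants[rep(seq_len(nrow(cfg$ssr_plants)),
                               cfg$ssr_plants$count), , drop = FALSE]
  n_plant <- nrow(plants)
  hosts <- sample(cfg$n_tus, n_plant)
  truth_ssr <- data.frame(tus_id = character(0), start = integer(0),
                          unit = character(0), repeat_count = integer(0),
                          stringsAsFactors = FALSE)
  for (i in seq_len(n_plant)) {
    h <- hosts[i]
    motif <- strrep(plants$unit[i], plants$repeat_count[i])
    m <- nchar(motif)
    if (len[h] < m + 60L) next
    pos <- sample(seq.int(30L, len[h] - m - 30L), 1L)
    # non-repeat guard bases prevent chance extension of the planted tract
    guard_l <- setdiff(c("A", "C", "G", "T"),
                       substr(plants$unit[i], nchar(plants$unit[i]),
                              nchar(plants$unit[i])))[1]
    guard_r <- setdiff(c("A", "C", "G", "T"),
                       substr(plants$unit[i], 1L, 1L))[1]
    substr(seqs[h], pos - 1L, pos - 1L) <- guard_l
    substr(seqs[h], pos, pos + m - 1L) <- motif
    substr(seqs[h], pos + m, pos + m) <- guard_r
    truth_ssr <- rbind(truth_ssr, data.frame(
      tus_id = ids[h], start = pos, unit = plants$unit[i],
      repeat_count = plants$repeat_count[i], stringsAsFactors = FALSE))
  }
  n_tail <- round(cfg$polya_fraction * cfg$n_tus)
  tail_hosts <- sample(setdiff(seq_len(cfg$n_tus), hosts),
                       min(n_tail, cfg$n_tus - n_plant))
  tail_len <- sample(12:25, length(tail_hosts), replace = TRUE)
  for (i in seq_along(tail_hosts)) {
    h <- tail_hosts[i]
    # strip any chance 3' A-run so the planted tail is exactly the
    # trimmable run, then append it
    seqs[h] <- paste0(sub("A+$", "", seqs[h]), strrep("A", tail_len[i]))
  }
  list(tus = seq_set(ids, seqs),
       truth = list(
         ssrs = truth_ssr,
         polya = data.frame(tus_id = ids[tail_hosts], tail_len = tail_len,
                            stringsAsFactors = FALSE)))
}

#' Simulate a toy genome with known intron structure plus GFF3
#'
#' Selected transcripts are written onto the genome as exon blocks
#' separated by planted introns (all within the 5000 bp cap); selected
#' intronless transcript pairs are placed within 1000 bp of each other
#' to exercise the transcribed-unit merge rule. The GFF3 encodes the
#' exact exon blocks (`match`/`match_part` with `Target`).
#'
#' @param cfg from [sim_config()].
#' @param tus sequence set from [simulate_transcriptome()].
#' @param gff_path where to write the GFF3.
#' @param genome_id name of the single genome sequence (default "chr1").
#' @return list: `genome` (sequence set of one record), `blocks` (exon
#'   block data.frame as from [read_spliced_alignments()]), `truth` with
#'   `introns` (`tus_id`, `junction`, `length`, `donor`, `acceptor`) and
#'   `close_pairs` (`tus_a`, `tus_b`, `gap`).
#' @export
simulate_genome_and_alignments <- function(cfg, tus, gff_path,
                                           genome_id = "chr1") {
  set.seed(cfg$seed + 1L)
  len <- nchar(tus$seq)
  eligible <- which(len >= 300L)
  genes <- utils::head(eligible, cfg$n_genes_with_introns)
  pair_pool <- setdiff(eligible, genes)
  pairs <- utils::head(pair_pool, 2L * cfg$n_close_pairs)
  cursor <- 1L
  pieces <- character(0)
  blocks <- list()
  introns <- list()
  close_pairs <- list()
  emit <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    start <- cursor
    cursor <<- cursor + nchar(piece)
    start
  }
  spacer <- function(n) emit(random_dna(n))
  for (g in genes) {
    spacer(sample(500:1500, 1L))
    L <- len[g]
    n_exon <- sample(2:max(2L, min(4L, L %/% 90L)), 1L)
    # random exon lengths with an 80-nt floor each (primer room)
    extra <- L - 80L * n_exon
    split_pts <- sort(stats::runif(n_exon - 1L))
    parts <- round(diff(c(0, split_pts, 1)) * extra)
    parts[n_exon] <- extra - sum(parts[-n_exon])
    exon_len <- 80L + as.integer(parts)
    tends <- cumsum(exon_len)
    tstarts <- c(1L, utils::head(tends, -1L) + 1L)
    for (e in seq_len(n_exon)) {
      gstart <- emit(substr(tus$seq[g], tstarts[e], tends[e]))
      blocks[[length(blocks) + 1L]] <- data.frame(
        aln_id = paste0("aln_", tus$id[g]), tus_id = tus$id[g],
        genome_seq_id = genome_id, strand = "+", gstart = gstart,
        gend = gstart + (tends[e] - tstarts[e]), tstart = tstarts[e],
        tend = tends[e], score = 1000, stringsAsFactors = FALSE)
      if (e < n_exon) {
        ilen <- sample(cfg$intron_len_min:cfg$intron_len_max, 1L)
        donor <- cursor
        spacer(ilen)
        introns[[length(introns) + 1L]] <- data.frame(
          tus_id = tus$id[g], junction = tends[e], length = ilen,
          donor = donor, acceptor = donor + ilen - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_len(length(pairs) %/% 2L)) {
    a <- pairs[2L * k - 1L]; b <- pairs[2L * k]
    spacer(sample(2000:3000, 1L))
    ga <- emit(tus$seq[a])
    gap <- sample(200:900, 1L)
    spacer(gap)
    gb <- emit(tus$seq[b])
    for (x in list(c(a, ga), c(b, gb))) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        aln_id = paste0("aln_", tus$id[x[1]]), tus_id = tus$id[x[1]],
        genome_seq_id = genome_id, strand = "+", gstart = x[2],
        gend = x[2] + len[x[1]] - 1L, tstart = 1L, tend = len[x[1]],
        score = 1000, stringsAsFactors = FALSE)
    }
    close_pairs[[length(close_pairs) + 1L]] <- data.frame(
      tus_a = tus$id[a], tus_b = tus$id[b], gap = gap,
      stringsAsFactors = FALSE)
  }
  spacer(500L)
  blocks <- do.call(rbind, blocks)
  write_alignment_gff3(blocks, gff_path)
  list(genome = seq_set(genome_id, paste(pieces, collapse = "")),
       blocks = blocks,
       truth = list(introns = do.call(rbind, introns),
                    close_pairs = do.call(rbind, close_pairs)))
}

#' Write exon blocks as GFF3 match/match_part features
#' @param blocks exon block data.frame.
#' @param path output GFF3.
#' @export
write_alignment_gff3 <- function(blocks, path) {
  by_aln <- split(blocks, blocks$aln_id)
  lines <- c("##gff-version 3")
  for (aln in by_aln) {
    lines <- c(lines, sprintf(
      "%s\tsim\tmatch\t%d\t%d\t%s\t%s\t.\tID=%s;Target=%s %d %d",
      aln$genome_seq_id[1], min(aln$gstart), max(aln$gend),
      aln$score[1], aln$strand[1], aln$aln_id[1], aln$tus_id[1],
      min(aln$tstart), max(aln$tend)))
    lines <- c(lines, sprintf(
      "%s\tsim\tmatch_part\t%d\t%d\t%s\t%s\t.\tParent=%s;Target=%s %d %d",
      aln$genome_seq_id, aln$gstart, aln$gend, aln$score, aln$strand,
      aln$aln_id, aln$tus_id, aln$tstart, aln$tend))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plant inter-genotype variants and derive the second haplotype
#'
#' @param cfg from [sim_config()].
#' @param tus sequence set (genotype-1 haplotype).
#' @return list: `hap2` (sequence set with substitutions applied) and
#'   `variants` (data.frame `tus_id`, `pos`, `ref`, `alt`,
#'   `designed_freq`).
#' @export
plant_variants <- function(cfg, tus) {
  set.seed(cfg$seed + 2L)
  len <- nchar(tus$seq)
  n <- nrow(tus)
  hosts <- sample(rep(seq_len(n), length.out = cfg$n_variants))
  hap2 <- tus$seq
  if (cfg$n_variants == 0L) {
    return(list(hap2 = seq_set(tus$id, hap2),
                variants = data.frame(tus_id = character(),
                                      pos = integer(), ref = character(),
                                      alt = character(),
                                      designed_freq = numeric(),
                                      stringsAsFactors = FALSE)))
  }
  vars <- list()
  for (i in seq_len(cfg$n_variants)) {
    h <- hosts[i]
    pos <- sample(seq.int(5L, len[h] - 5L), 1L)
    ref <- substr(tus$seq[h], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    substr(hap2[h], pos, pos) <- alt
    vars[[i]] <- data.frame(tus_id = tus$id[h], pos = pos, ref = ref,
                            alt = alt, designed_freq = cfg$variant_freq,
                            stringsAsFactors = FALSE)
  }
  vars <- do.call(rbind, vars)
  vars <- vars[!duplicated(vars[c("tus_id", "pos")]), , drop = FALSE]
  list(hap2 = seq_set(tus$id, hap2), variants = vars)
}

#' Simulate two tag libraries from two haplotypes
#'
#' Transcript abundances are log-normal; planted log2 fold changes are
#' split symmetrically between the libraries
#' (`w1 = a * 2^(fc/2)`, `w2 = a * 2^(-fc/2)`). Tags of `tag_length` nt
#' are drawn from uniform positions and strands, with independent
#' per-base substitution errors at `error_rate`.
#'
#' @param cfg from [sim_config()].
#' @param hap1,hap2 the two genotype haplotype sequence sets.
#' @return list: `tags1`, `tags2` (data.frames `id`, `seq`), `truth`
#'   with `fold_changes` (`tus_id`, `log2fc`), `abundance`, and true
#'   sampled counts `n1`, `n2` per TUS.
#' @export
simulate_tags <- function(cfg, hap1, hap2) {
  set.seed(cfg$seed + 3L)
  n <- nrow(hap1)
  len <- nchar(hap1$seq)
  a <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
  fc <- numeric(n)
  fc_hosts <- sample(which(len >= cfg$tag_length + 10L),
                     sum(cfg$fold_changes$n_genes))
  fc[fc_hosts] <- rep(cfg$fold_changes$log2fc, cfg$fold_changes$n_genes)
  w1 <- a * 2^(fc / 2)
  w2 <- a * 2^(-fc / 2)
  usable <- len >= cfg$tag_length
  w1[!usable] <- 0
  w2[!usable] <- 0
  draw <- function(weights, hap, N, lib) {
    idx <- sample.int(n, N, replace = TRUE, prob = weights)
    pos <- floor(stats::runif(N) * (len[idx] - cfg$tag_length + 1L)) + 1L
    seqs <- substring(hap$seq[idx], pos, pos + cfg$tag_length - 1L)
    minus <- stats::runif(N) < 0.5
    seqs[minus] <- revcomp(seqs[minus])
    # per-base substitution errors: presampled positions and offsets
    n_err <- stats::rbinom(N, cfg$tag_length, cfg$error_rate)
    which_err <- which(n_err > 0L)
    if (length(which_err)) {
      tag_of <- rep(which_err, n_err[which_err])
      pos_of <- unlist(lapply(n_err[which_err], sample.int,
                              n = cfg$tag_length), use.names = FALSE)
      shift <- sample.int(3L, length(tag_of), replace = TRUE)
      alpha <- c("A", "C", "G", "T")
      for (e in seq_along(tag_of)) {
        old <- match(substr(seqs[tag_of[e]], pos_of[e], pos_of[e]), alpha)
        substr(seqs[tag_of[e]], pos_of[e], pos_of[e]) <-
          alpha[(old - 1L + shift[e]) %% 4L + 1L]
      }
    }
    list(tags = data.frame(id = sprintf("%s_tag%07d", lib, seq_len(N)),
                           seq = seqs, stringsAsFactors = FALSE),
         counts = tabulate(idx, nbins = n))
  }
  d1 <- draw(w1, hap1, cfg$N1, "g1")
  d2 <- draw(w2, hap2, cfg$N2, "g2")
  list(tags1 = d1$tags, tags2 = d2$tags,
       truth = list(fold_changes = data.frame(tus_id = hap1$id, log2fc = fc,
                                              stringsAsFactors = FALSE),
                    abundance = a, n1 = d1$counts, n2 = d2$counts))
}

#' Construct six-species ortholog hit tables with designed outcomes
#'
#' Hit tables are built directly with controlled E-values and bitscores
#' so the COS cascade is exercised against a known truth table: a
#' designed number of query families fail each stage.
#'
#' @param seed RNG seed.
#' @param n_families total query families (default 50).
#' @param n_fail_stage1 families missing a strong hit in one species
#'   (default 10).
#' @param n_fail_stage2 families with a discordant annotation in one
#'   species (default 10).
#' @param n_paralog families with a within-species near-best duplicate
#'   subject (default 5).
#' @param n_prior_cos families matching the prior COS set (default 5).
#' @param qlen query length used throughout (default 400).
#' @return list: `species_hits` (list of 6), `annotations`,
#'   `prior_cos_hits`, `qlens`, `truth` with the designed per-stage
#'   counts `stages` (n1..n4) and the member sets.
#' @export
simulate_ortholog_hits <- function(seed = 1L, n_families = 50L,
                                   n_fail_stage1 = 10L,
                                   n_fail_stage2 = 10L, n_paralog = 5L,
                                   n_prior_cos = 5L, qlen = 400L) {
  stopifnot(n_fail_stage1 + n_fail_stage2 + n_paralog + n_prior_cos <=
              n_families)
  set.seed(seed)
  q <- sprintf("Q%03d", seq_len(n_families))
  grp <- rep("pass", n_families)
  grp[seq_len(n_fail_stage1)] <- "fail1"
  grp[n_fail_stage1 + seq_len(n_fail_stage2)] <- "fail2"
  grp[n_fail_stage1 + n_fail_stage2 + seq_len(n_paralog)] <- "paralog"
  grp[n_fail_stage1 + n_fail_stage2 + n_paralog +
        seq_len(n_prior_cos)] <- "prior"
  hit_row <- function(query, subject, evalue, bitscore) {
    data.frame(query = query, subject = subject, pct_identity = 90,
               aln_len = qlen, mismatches = 10, gap_opens = 0, qstart = 1,
               qend = qlen, sstart = 1, send = qlen, evalue = evalue,
               bitscore = bitscore, stringsAsFactors = FALSE)
  }
  annotations <- character(0)
  species_hits <- vector("list", 6L)
  for (s in 1:6) {
    rows <- list()
    for (i in seq_len(n_families)) {
      subj <- sprintf("sp%d_%s_orth", s, q[i])
      ev <- 1e-40
      if (grp[i] == "fail1" && s == 1L) ev <- 1e-20  # below stage-1 cutoff
      rows[[length(rows) + 1L]] <- hit_row(q[i], subj, ev, 200)
      ann <- paste("protein family", i)
      if (grp[i] == "fail2" && s == 2L) ann <- paste("different protein", i)
      annotations[subj] <- ann
      if (grp[i] == "paralog" && s == 3L) {
        dup <- sprintf("sp%d_%s_dup", s, q[i])
        rows[[length(rows) + 1L]] <- hit_row(q[i], dup, 1e-38, 195)
        annotations[dup] <- ann
      }
    }
    species_hits[[s]] <- do.call(rbind, rows)
  }
  prior_rows <- lapply(q[grp == "prior"], function(qq) {
    h <- hit_row(qq, "priorCOS_1", 1e-20, 150)
    h$aln_len <- round(0.5 * qlen)
    h
  })
  prior_cos_hits <- if (length(prior_rows)) do.call(rbind, prior_rows) else
    utils::head(hit_row("x", "y", 1, 1), 0L)
  n1 <- sum(grp != "fail1")
  n2 <- sum(!grp %in% c("fail1", "fail2"))
  n3 <- sum(grp %in% c("pass", "prior"))
  n4 <- sum(grp == "pass")
  list(species_hits = species_hits, annotations = annotations,
       prior_cos_hits = prior_cos_hits,
       qlens = stats::setNames(rep(qlen, n_families), q),
       truth = list(stages = c(n1 = n1, n2 = n2, n3 = n3, n4 = n4),
                    groups = stats::setNames(grp, q)))
}
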