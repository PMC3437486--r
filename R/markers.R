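# Marker design from spliced transcript-to-genome alignments and
# similarity-hit cascades: intron inference, intron-spanning (ISR)
# primers, transcribed-unit merging, generic hit filters and the
# six-species conserved-ortholog (COS) cascade.

#' Read spliced alignments from GFF3
#'
#' Expects `match` features with `match_part` children carrying `Target`
#' attributes (`tus_id tstart tend`), the standard encoding of spliced
#' transcript-to-genome alignments. Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return data.frame of exon blocks: `aln_id`, `tus_id`,
#'   `genome_seq_id`, `strand`, `gstart`, `gend`, `tstart`, `tend`,
#'   `score`, ordered by alignment then genomic start.
#' @export
read_spliced_alignments <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  part <- gr[gr$type == "match_part"]
  tgt <- as.character(part$Target)
  f <- strsplit(tgt, " ", fixed = TRUE)
  parent <- vapply(part$Parent, function(p) p[[1]], "")
  score <- part$score
  match_score <- stats::setNames(gr$score[gr$type == "match"],
                                 gr$ID[gr$type == "match"])
  df <- data.frame(
    aln_id = parent,
    tus_id = vapply(f, `[`, "", 1L),
    genome_seq_id = as.character(GenomicRanges::seqnames(part)),
    strand = as.character(GenomicRanges::strand(part)),
    gstart = GenomicRanges::start(part),
    gend = GenomicRanges::end(part),
    tstart = as.integer(vapply(f, `[`, "", 2L)),
    tend = as.integer(vapply(f, `[`, "", 3L)),
    score = as.numeric(match_score[parent]),
    stringsAsFactors = FALSE)
  df[order(df$aln_id, df$gstart), , drop = FALSE]
}

#' Drop alignments scoring below half the best score per TUS
#'
#' Mirrors the upstream spliced-aligner convention of retaining only
#' alignments with scores at least 50% of the top-scoring match for the
#' same transcript; applied as an input filter before ISR design.
#'
#' @param blocks block data.frame from [read_spliced_alignments()].
#' @param min_frac fraction of the per-TUS best score (default 0.5).
#' @return filtered block data.frame.
#' @export
filter_alignment_score <- function(blocks, min_frac = 0.5) {
  if (nrow(blocks) == 0L) return(blocks)
  per_aln <- unique(blocks[, c("aln_id", "tus_id", "score")])
  best <- tapply(per_aln$score, per_aln$tus_id, max)
  keep_aln <- per_aln$aln_id[per_aln$score >= min_frac * best[per_aln$tus_id]]
  blocks[blocks$aln_id %in% keep_aln, , drop = FALSE]
}

#' Infer introns from one spliced alignment
#'
#' Each genomic gap between consecutive exon blocks of length between
#' `min_intron` and `max_intron` is an intron; smaller gaps are treated
#' as alignment indels and larger gaps split the alignment (no intron
#' emitted in either case).
#'
#' @param blocks data.frame of one alignment's exon blocks, ordered by
#'   genomic start (`gstart`, `gend`, `tstart`, `tend`).
#' @param min_intron default 40 nt.
#' @param max_intron default 5000 nt.
#' @return data.frame: `donor`, `acceptor` (genomic first/last intron
#'   base), `length`, `junction` (transcript position of the exon base
#'   immediately 5' of the intron), `exon_before` (block index).
#' @export
infer_introns <- function(blocks, min_intron = 40L, max_intron = 5000L) {
  n <- nrow(blocks)
  out <- data.frame(donor = integer(), acceptor = integer(),
                    length = integer(), junction = integer(),
                    exon_before = integer())
  if (n < 2L) return(out)
  gap <- blocks$gstart[-1] - blocks$gend[-n] - 1L
  ok <- gap >= min_intron & gap <= max_intron
  data.frame(donor = blocks$gend[-n][ok] + 1L,
             acceptor = blocks$gstart[-1][ok] - 1L,
             length = gap[ok],
             junction = blocks$tend[-n][ok],
             exon_before = which(ok))
}

#' Group alignments into transcribed units
#'
#' Alignments on one genome sequence and strand whose genomic spans are
#' separated by at most `max_gap` uncovered bp are grouped transitively
#' into one transcribed unit (likely one gene). Grouping is
#' order-invariant: spans are sorted internally.
#'
#' @param spans data.frame with `aln_id`, `gstart`, `gend` for one
#'   genome sequence and strand.
#' @param max_gap maximum uncovered gap in bp (default 1000).
#' @return data.frame `aln_id`, `unit` (integer group id).
#' @export
merge_transcribed_units <- function(spans, max_gap = 1000L) {
  o <- order(spans$gstart, spans$gend)
  s <- spans[o, , drop = FALSE]
  unit <- integer(nrow(s))
  if (nrow(s)) {
    unit[1] <- 1L
    run_end <- s$gend[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$gstart[i] - run_end - 1L > max_gap) {
        unit[i] <- unit[i - 1L] + 1L
        run_end <- s$gend[i]
      } else {
        unit[i] <- unit[i - 1L]
        run_end <- max(run_end, s$gend[i])
      }
    }
  }
  data.frame(aln_id = s$aln_id, unit = unit, stringsAsFactors = FALSE)
}

#' Design intron-spanning (ISR) primer pairs
#'
#' For each inferred intron, a primer pair is sought with the left
#' primer entirely within the exon 5' of the junction and the right
#' primer entirely within the exon 3' of it (transcript coordinates), so
#' the transcript product spans exactly that junction and the genomic
#' product differs by the intron length:
#' `product_size_genomic = product_size_transcript + intron length`.
#'
#' @param tus_sequence transcript sequence the alignment refers to.
#' @param blocks exon blocks of one alignment (see [infer_introns()]).
#' @param introns from [infer_introns()] on the same blocks.
#' @param params primer parameters; defaults to [primer_params()] with
#'   product size 80-400 transcript bp.
#' @return data.frame with one row per designable junction (`junction`,
#'   `intron_length`, primer fields, `product_size_transcript`,
#'   `product_size_genomic`, `marker_type = "ISR"`); junctions with no
#'   feasible pair are skipped (reasons in attribute `"skipped"`).
#' @export
design_isr <- function(tus_sequence, blocks, introns,
                       params = primer_params(product_min = 80L,
                                              product_max = 400L)) {
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(introns))) {
    b <- introns$exon_before[i]
    exon_l <- c(blocks$tstart[b], blocks$tend[b])
    exon_r <- c(blocks$tstart[b + 1L], blocks$tend[b + 1L])
    left <- primer_candidates(tus_sequence, exon_l[1], exon_l[2], params)
    right <- primer_candidates(tus_sequence, exon_r[1], exon_r[2], params,
                               right = TRUE)
    bp <- best_pair(left, right, params)
    if (!is.null(bp$failure)) {
      skipped <- c(skipped, stats::setNames(bp$failure,
                                            introns$junction[i]))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      junction = introns$junction[i],
      intron_length = introns$length[i],
      left_seq = left$seq[bp$i], right_seq = right$seq[bp$j],
      left_pos = left$start[bp$i], right_pos = right$end[bp$j],
      tm_left = left$tm[bp$i], tm_right = right$tm[bp$j],
      gc_left = left$gc[bp$i], gc_right = right$gc[bp$j],
      product_size_transcript = bp$product,
      product_size_genomic = bp$product + introns$length[i],
      marker_type = "ISR", stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(junction = integer(), intron_length = integer(),
               left_seq = character(), right_seq = character(),
               left_pos = integer(), right_pos = integer(),
               tm_left = numeric(), tm_right = numeric(),
               gc_left = numeric(), gc_right = numeric(),
               product_size_transcript = integer(),
               product_size_genomic = integer(),
               marker_type = character(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Generic similarity-hit filter cascade
#'
#' A query survives iff at least one of its hits meets every supplied
#' threshold: `evalue <= evalue_max`, query coverage
#' `100 * aln_len / qlen >= min_qcov_pct`, identity
#' `pct_identity >= min_identity_pct`, and aligned length
#' `aln_len >= min_qaln_len`. Unsupplied thresholds are not applied.
#'
#' @param hits hit data.frame ([read_hit_table()]).
#' @param qlens named query lengths (required when `min_qcov_pct` is
#'   supplied).
#' @param evalue_max E-value ceiling.
#' @param min_qcov_pct optional query-coverage floor (percent).
#' @param min_identity_pct optional identity floor (percent, inclusive).
#' @param min_qaln_len optional aligned-length floor (nt).
#' @return list: `queries` (surviving), `subjects` (distinct matched
#'   subjects of surviving hits), `n_queries`, `n_subjects`.
#' @export
filter_hits_cascade <- function(hits, qlens = NULL, evalue_max,
                                min_qcov_pct = NULL,
                                min_identity_pct = NULL,
                                min_qaln_len = NULL) {
  pass <- hits$evalue <= evalue_max
  if (!is.null(min_qcov_pct)) {
    if (is.null(qlens)) stop("query lengths required for coverage filtering")
    ql <- qlens[hits$query]
    if (anyNA(ql)) stop("unknown query length for: ",
                        hits$query[is.na(ql)][1])
    pass <- pass & 100 * hits$aln_len / ql >= min_qcov_pct
  }
  if (!is.null(min_identity_pct)) {
    pass <- pass & hits$pct_identity >= min_identity_pct
  }
  if (!is.null(min_qaln_len)) pass <- pass & hits$aln_len >= min_qaln_len
  list(queries = unique(hits$query[pass]),
       subjects = unique(hits$subject[pass]),
       n_queries = length(unique(hits$query[pass])),
       n_subjects = length(unique(hits$subject[pass])))
}

#' Normalize a functional annotation for identity comparison
#'
#' Case-folded, punctuation-stripped, with isoform/fragment/partial
#' suffixes removed and whitespace squeezed.
#'
#' @param x character vector of descriptions.
#' @return normalized descriptions.
#' @export
normalize_annotation <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\b(isoform|fragment|partial)\\b\\s*\\w*", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Conserved-ortholog (COS) candidate cascade
#'
#' Four stages over six per-species hit tables: (1) keep queries with at
#' least one hit at `evalue <= stage1_evalue` in every species; (2) keep
#' those whose normalized best-hit annotation is identical across all
#' six species; (3) remove queries flagged paralogous -- a query is
#' flagged iff, in any single species, it has two or more distinct
#' subjects at `evalue <= stage1_evalue` with bitscore at least
#' `paralog_bitscore_frac` of that species' best hit for the query; (4)
#' remove queries matching a prior COS set at `evalue <= stage4_evalue`
#' and query coverage at least `stage4_min_qcov_pct` percent.
#'
#' @param species_hits list of exactly six hit data.frames.
#' @param annotations named character vector: subject id -> functional
#'   annotation.
#' @param prior_cos_hits hit data.frame against the prior COS set (may
#'   have zero rows).
#' @param qlens named query lengths (stage 4 coverage).
#' @param stage1_evalue default 1e-30.
#' @param stage4_evalue default 1e-5.
#' @param stage4_min_qcov_pct default 25.
#' @param paralog_bitscore_frac default 0.9.
#' @return list: `candidates` (final query set), `stages` = named
#'   integer vector (n1, n2, n3, n4), and the per-stage query sets.
#' @export
cos_cascade <- function(species_hits, annotations, prior_cos_hits, qlens,
                        stage1_evalue = 1e-30, stage4_evalue = 1e-5,
                        stage4_min_qcov_pct = 25,
                        paralog_bitscore_frac = 0.9) {
  if (length(species_hits) != 6L) {
    stop("exactly six species hit tables are required, got ",
         length(species_hits))
  }
  sig <- lapply(species_hits, function(h) {
    h[h$evalue <= stage1_evalue, , drop = FALSE]
  })
  stage1 <- Reduce(intersect, lapply(sig, function(h) unique(h$query)))
  # stage 2: identical normalized best-hit annotation across species
  best_annot <- function(h, q) {
    hh <- h[h$query == q, , drop = FALSE]
    hh <- hh[order(hh$evalue, -hh$bitscore), , drop = FALSE]
    ann <- annotations[hh$subject[1]]
    if (is.na(ann)) NA_character_ else normalize_annotation(ann)
  }
  stage2 <- stage1[vapply(stage1, function(q) {
    anns <- vapply(sig, best_annot, "", q = q)
    !anyNA(anns) && length(unique(anns)) == 1L
  }, NA)]
  # stage 3: paralog removal
  is_paralog <- function(q) {
    any(vapply(sig, function(h) {
      hh <- h[h$query == q, , drop = FALSE]
      if (nrow(hh) == 0L) return(FALSE)
      top <- max(hh$bitscore)
      length(unique(hh$subject[hh$bitscore >= paralog_bitscore_frac * top])) >= 2L
    }, NA))
  }
  stage3 <- stage2[!vapply(stage2, is_paralog, NA)]
  # stage 4: prior-COS exclusion
  prior <- filter_hits_cascade(prior_cos_hits, qlens = qlens,
                               evalue_max = stage4_evalue,
                               min_qcov_pct = stage4_min_qcov_pct)
  stage4 <- setdiff(stage3, prior$queries)
  list(candidates = stage4,
       stages = c(n1 = length(stage1), n2 = length(stage2),
                  n3 = length(stage3), n4 = length(stage4)),
       stage1 = stage1, stage2 = stage2, stage3 = stage3, stage4 = stage4)
}
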