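# Inter-genotype variant mining from tag pileups.
#
# The TUS assembly derives from genotype 1, so "allele frequency" is
# operationalized as the alternate-allele fraction among the reads of the
# other genotype (genotype 2), and the depth used for filtering and
# binning is the depth in that same read set -- frequency numerator,
# denominator and depth filter all refer to one pileup.

BASES5 <- c("A", "C", "G", "T", "N")

#' Build a per-position base-count pileup from tag placements
#'
#' Placements should already be restricted to the `unique_only` policy
#' (single equal-best placement). Minus-strand tags contribute their
#' reverse complement. Positions with zero depth are omitted.
#'
#' @param alignments placement data.frame from [map_tags()] (one
#'   library), filtered to the rows to stack.
#' @param tags character vector of tag sequences indexed by
#'   `alignments$tag`.
#' @param tus sequence-set data.frame the placements refer to.
#' @return data.frame with `tus_id`, `pos`, `A`, `C`, `G`, `T`, `N`,
#'   `depth` for every covered position.
#' @export
build_pileup <- function(alignments, tags, tus) {
  L <- if (nrow(alignments)) nchar(tags[alignments$tag[1]]) else 0L
  tus_len <- stats::setNames(nchar(tus$seq), tus$id)
  if (nrow(alignments)) {
    end <- alignments$pos + L - 1L
    if (any(alignments$pos < 1L) ||
        any(end > tus_len[alignments$tus_id])) {
      stop("alignment extends beyond TUS bounds")
    }
  }
  empty <- data.frame(tus_id = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      N = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  oriented <- tags[alignments$tag]
  minus <- alignments$strand == "-"
  if (any(minus)) oriented[minus] <- revcomp(oriented[minus])
  nal <- nrow(alignments)
  tus_idx <- match(alignments$tus_id, tus$id)
  base_chr <- strsplit(paste(oriented, collapse = ""), "", fixed = TRUE)[[1]]
  base_int <- match(base_chr, BASES5)
  pos_all <- rep(alignments$pos, each = L) + rep.int(0:(L - 1L), nal)
  tus_all <- rep(tus_idx, each = L)
  lmax <- max(tus_len)
  key <- ((tus_all - 1) * lmax + (pos_all - 1)) * 5 + base_int
  counts <- tabulate(key, nbins = length(tus$id) * lmax * 5)
  nz_cell <- which(counts > 0L)
  colkey <- (nz_cell - 1L) %/% 5L          # one per (tus, pos)
  b <- (nz_cell - 1L) %% 5L + 1L
  ucol <- unique(colkey)
  m <- matrix(0L, nrow = length(ucol), ncol = 5L,
              dimnames = list(NULL, BASES5))
  ridx <- match(colkey, ucol)
  m[cbind(ridx, b)] <- counts[nz_cell]
  out <- data.frame(tus_id = tus$id[ucol %/% lmax + 1L],
                    pos = ucol %% lmax + 1L, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  out$depth <- rowSums(m)
  out <- out[order(match(out$tus_id, tus$id), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call inter-genotype variant candidates from two pileups
#'
#' At every position covered in both genotypes where genotype 2 shows an
#' allele differing from the TUS consensus, the alternate-allele fraction
#' and depth are computed in the genotype-2 pileup. Positions with depth
#' below `min_depth` are not emitted at all; everything else is emitted
#' and binned (frequency and depth bins), with `pass_filter` marking the
#' candidates satisfying `alt_freq > min_freq` and
#' `min_depth <= depth < max_depth_exclusive`. Filter-passing candidates
#' get a confidence tier via [assign_tier()].
#'
#' @param pileup_g1,pileup_g2 pileups from [build_pileup()].
#' @param tus sequence-set data.frame (consensus source).
#' @param min_depth default 3 (inclusive).
#' @param max_depth_exclusive default 500 (exclusive).
#' @param min_freq default 0.1 (strict).
#' @return data.frame of candidates: `tus_id`, `pos`, `ref_allele`,
#'   `alt_allele`, `alt_freq`, `depth`, `freq_bin`, `depth_bin`,
#'   `pass_filter`, `well_supported`, `stringent`, `tier`.
#' @export
call_candidates <- function(pileup_g1, pileup_g2, tus, min_depth = 3L,
                            max_depth_exclusive = 500L, min_freq = 0.1) {
  key1 <- paste(pileup_g1$tus_id, pileup_g1$pos)
  key2 <- paste(pileup_g2$tus_id, pileup_g2$pos)
  p2 <- pileup_g2[key2 %in% key1, , drop = FALSE]
  empty <- data.frame(tus_id = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      alt_freq = numeric(), depth = integer(),
                      freq_bin = character(), depth_bin = character(),
                      pass_filter = logical(), well_supported = logical(),
                      stringent = logical(), tier = character(),
                      stringsAsFactors = FALSE)
  if (nrow(p2) == 0L) return(empty)
  ref <- substring(tus$seq[match(p2$tus_id, tus$id)], p2$pos, p2$pos)
  cm <- as.matrix(p2[, c("A", "C", "G", "T")])
  # zero out the reference column, then take the top alternate base
  cm[cbind(seq_len(nrow(cm)), match(ref, c("A", "C", "G", "T")))] <- 0L
  alt_count <- apply(cm, 1L, max)
  alt_base <- c("A", "C", "G", "T")[apply(cm, 1L, which.max)]
  keep <- alt_count > 0L & p2$depth >= min_depth
  if (!any(keep)) return(empty)
  out <- data.frame(tus_id = p2$tus_id[keep], pos = p2$pos[keep],
                    ref_allele = ref[keep], alt_allele = alt_base[keep],
                    alt_freq = alt_count[keep] / p2$depth[keep],
                    depth = p2$depth[keep], stringsAsFactors = FALSE)
  bins <- bin_candidate(out$alt_freq, out$depth)
  out$freq_bin <- bins$freq_bin
  out$depth_bin <- bins$depth_bin
  out$pass_filter <- out$alt_freq > min_freq &
    out$depth < max_depth_exclusive
  out$well_supported <- out$pass_filter & out$alt_freq >= 0.9 &
    out$depth >= 3L
  out$stringent <- out$pass_filter & out$alt_freq > 0.60 & out$depth > 10L
  out$tier <- ifelse(!out$pass_filter, NA_character_, assign_tier(out$alt_freq, out$depth))
  rownames(out) <- NULL
  out
}

#' Frequency and depth bins for the classification matrix
#'
#' Frequency rows: `<0.1`, then `[0.10,0.20)` printed `0.10-0.19` and so
#' on, with 1.0 included in the top `0.90-1.0` row. Depth columns:
#' `3-10`, `11-100`, `101-500`, `>500` (strictly greater).
#'
#' @param alt_freq numeric in \[0,1\].
#' @param depth integer depth (>= 3).
#' @return list with character vectors `freq_bin`, `depth_bin`.
#' @export
bin_candidate <- function(alt_freq, depth) {
  band <- pmin(floor(10 * alt_freq), 9)
  freq_bin <- ifelse(alt_freq < 0.1, "<0.1",
                     ifelse(band == 9, "0.90-1.0",
                            sprintf("0.%d0-0.%d9", band, band)))
  depth_bin <- ifelse(depth > 500, ">500",
                      ifelse(depth >= 101, "101-500",
                             ifelse(depth >= 11, "11-100", "3-10")))
  list(freq_bin = freq_bin, depth_bin = depth_bin)
}

#' Confidence tier of a filter-passing candidate
#'
#' `stringent_high_confidence` iff `alt_freq > 0.60` and `depth > 10`;
#' otherwise `well_supported` iff `alt_freq >= 0.9` and `depth >= 3`;
#' otherwise `candidate`. The two named tiers overlap as definitions, so
#' [call_candidates()] also reports them as independent flags.
#'
#' @param alt_freq,depth candidate fields.
#' @return character vector of tiers.
#' @export
assign_tier <- function(alt_freq, depth) {
  ifelse(alt_freq > 0.60 & depth > 10, "stringent_high_confidence",
         ifelse(alt_freq >= 0.9 & depth >= 3, "well_supported",
                "candidate"))
}

#' Classification matrix of binned candidates
#'
#' @param candidates from [call_candidates()] (all emitted rows, not just
#'   filter-passing ones).
#' @return 10 x 4 integer matrix, frequency rows by depth columns, cells
#'   summing to the number of binned candidates.
#' @export
classification_matrix <- function(candidates) {
  freq_levels <- c("<0.1", sprintf("0.%d0-0.%d9", 1:8, 1:8), "0.90-1.0")
  depth_levels <- c(">500", "101-500", "11-100", "3-10")
  table(factor(candidates$freq_bin, levels = freq_levels),
        factor(candidates$depth_bin, levels = depth_levels))
}

#' Write variant candidates as VCF v4.2
#'
#' CHROM is the TUS id; INFO carries AF (alternate fraction in genotype
#' 2), DP (genotype-2 depth) and TIER. Input must be sorted by
#' (`tus_id`, `pos`).
#'
#' @param candidates filter-passing candidate rows.
#' @param tus sequence-set data.frame (for contig headers).
#' @param path output file.
#' @export
write_vcf <- function(candidates, tus, path) {
  o <- order(match(candidates$tus_id, tus$id), candidates$pos)
  if (!identical(o, seq_len(nrow(candidates)))) {
    stop("candidates must be sorted by (tus_id, pos)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tusmarkers",
    sprintf("##contig=<ID=%s,length=%d>", tus$id, nchar(tus$seq)),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction in genotype 2\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth in genotype 2\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Confidence tier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(candidates)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;DP=%d;TIER=%s",
                       candidates$tus_id, candidates$pos,
                       candidates$ref_allele, candidates$alt_allele,
                       candidates$alt_freq, candidates$depth,
                       candidates$tier), con)
  }
  invisible(path)
}
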