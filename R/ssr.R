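# SSR (simple sequence repeat) mining over TUS sets.
#
# Detection reports perfect tandem repeats of 1-6 nt units. Units are
# reported exactly as they occur on the given strand with no
# canonicalization: AG, GA, TC and CT are four different motifs, each
# tallied separately (an optional canonical grouping is available via
# canonical_unit() but is never applied by default).

#' Default minimum repeat numbers per unit length
#'
#' The canonical MISA profile: at least 10 repeats for mono-, 6 for di-
#' and 5 for tri- through hexa-nucleotide units.
#' @return integer vector of length 6, indexed by unit length.
#' @export
misa_min_repeats <- function() c(10L, 6L, 5L, 5L, 5L, 5L)

# TRUE iff the unit is not itself a whole-number repetition of a shorter
# unit (so an AT tract is reported as (AT)n, never as (ATAT)m).
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(unit, 1L, d), k %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect perfect SSRs in one sequence
#'
#' Scans all unit lengths 1-6 for maximal perfect tandem repeats meeting
#' the per-unit-length minimum repeat numbers. Motif spans are truncated
#' to whole repeat units (`total_length = unit length x repeat_count`).
#' Units that are repetitions of a shorter unit are suppressed, so each
#' repeat tract is reported once at its shortest period. Overlapping
#' candidates are resolved left to right, leftmost-maximal: at equal
#' start the longer tract wins, then the shorter unit.
#'
#' @param seq one normalized DNA string.
#' @param min_repeats integer vector of length 6 giving the minimum
#'   repeat number for unit lengths 1-6 (default [misa_min_repeats()]).
#' @param tus_id identifier recorded in the output (default `"seq"`).
#' @return data.frame with columns `tus_id`, `start`, `end`, `unit`,
#'   `unit_len`, `repeat_count`, `total_length`.
#' @export
find_ssrs <- function(seq, min_repeats = misa_min_repeats(), tus_id = "seq") {
  stopifnot(length(seq) == 1L, length(min_repeats) == 6L)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- list()
  for (k in 1:6) {
    if (n < k * min_repeats[k]) next
    match_next <- chars[seq_len(n - k)] == chars[seq_len(n - k) + k]
    # maximal runs of TRUE in match_next define period-k tandem regions
    r <- rle(match_next)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]
      tract_len <- r$lengths[j] + k          # full tandem span in nt
      count <- tract_len %/% k
      if (count < min_repeats[k]) next
      unit <- substr(seq, s, s + k - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (!is_primitive_unit(unit)) next
      cand[[length(cand) + 1L]] <- data.frame(
        tus_id = tus_id, start = s, end = s + count * k - 1L, unit = unit,
        unit_len = k, repeat_count = count, total_length = count * k,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(tus_id = character(), start = integer(),
                      end = integer(), unit = character(),
                      unit_len = integer(), repeat_count = integer(),
                      total_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, cand)
  out <- out[order(out$start, -out$total_length, out$unit_len), , drop = FALSE]
  keep <- logical(nrow(out))
  last_end <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- out$end[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect SSRs across a sequence set
#'
#' @param x sequence-set data.frame (`id`, `seq`).
#' @param min_repeats see [find_ssrs()].
#' @return row-bound motif data.frame, ordered by sequence then start.
#' @export
find_ssrs_set <- function(x, min_repeats = misa_min_repeats()) {
  res <- lapply(seq_len(nrow(x)), function(i) {
    find_ssrs(x$seq[i], min_repeats = min_repeats, tus_id = x$id[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag compound SSRs
#'
#' Adjacent motifs on the same sequence separated by at most
#' `max_interruption` nt form a compound group (transitively). Member
#' motifs are retained and counted individually; the group id and span
#' are recorded on each member.
#'
#' @param motifs motif data.frame sorted by (`tus_id`, `start`).
#' @param max_interruption maximum interruption in nt (default 100, the
#'   MISA convention).
#' @return motifs with added columns `compound` (flag), `compound_id`
#'   (NA for non-compound), `compound_start`, `compound_end`.
#' @export
merge_compound <- function(motifs, max_interruption = 100L) {
  n <- nrow(motifs)
  motifs$compound <- logical(n)
  motifs$compound_id <- rep(NA_integer_, n)
  motifs$compound_start <- rep(NA_integer_, n)
  motifs$compound_end <- rep(NA_integer_, n)
  if (n == 0L) return(motifs)
  o <- order(motifs$tus_id, motifs$start)
  motifs <- motifs[o, , drop = FALSE]
  grp <- integer(n)
  g <- 1L
  grp[1] <- g
  for (i in seq_len(n)[-1]) {
    same <- motifs$tus_id[i] == motifs$tus_id[i - 1L]
    gap <- motifs$start[i] - motifs$end[i - 1L] - 1L
    if (!(same && gap <= max_interruption)) g <- g + 1L
    grp[i] <- g
  }
  sizes <- table(grp)
  in_compound <- sizes[as.character(grp)] >= 2L
  motifs$compound <- as.vector(in_compound)
  cid <- 0L
  for (gg in unique(grp[motifs$compound])) {
    cid <- cid + 1L
    ix <- grp == gg
    motifs$compound_id[ix] <- cid
    motifs$compound_start[ix] <- min(motifs$start[ix])
    motifs$compound_end[ix] <- max(motifs$end[ix])
  }
  rownames(motifs) <- NULL
  motifs
}

#' Assign SSR class
#'
#' Class I: total repeat tract at least `class1_min_length` nt (default
#' 20, the long-hypervariable convention); Class II otherwise.
#'
#' @param total_length integer vector of tract lengths.
#' @param class1_min_length boundary, inclusive (default 20).
#' @return character vector `"I"`/`"II"`.
#' @export
classify_ssr <- function(total_length, class1_min_length = 20L) {
  ifelse(total_length >= class1_min_length, "I", "II")
}

#' Filter SSR primer candidates
#'
#' A motif is retained as a marker candidate iff its unit length is at
#' least 2 (mono-nucleotide repeats excluded), primer design succeeded,
#' and the predicted product is at least 100 bp.
#'
#' @param motifs motif data.frame with a `unit_len` column.
#' @param design data.frame aligned row-by-row with `motifs`, columns
#'   `success` (logical) and `product_size` (nt, NA on failure).
#' @return logical vector, `TRUE` = retained.
#' @export
filter_marker_candidates <- function(motifs, design) {
  stopifnot(nrow(motifs) == nrow(design))
  motifs$unit_len >= 2L & design$success &
    !is.na(design$product_size) & design$product_size >= 100L
}

#' Redundancy screen against previously published marker sources
#'
#' A candidate is dropped iff it has a hit to the prior-marker source set
#' with `evalue <= evalue_max`, query coverage (`100 * aln_len / qlen`)
#' at least `min_qcov_pct`, and percent identity strictly above
#' `min_identity_pct`.
#'
#' @param candidates character vector of candidate query ids.
#' @param hits hit data.frame ([read_hit_table()]); every hit query must
#'   be a known candidate.
#' @param qlens named integer vector of query lengths.
#' @param evalue_max default 1e-5.
#' @param min_qcov_pct default 30.
#' @param min_identity_pct default 90 (strict inequality).
#' @return character vector of nonredundant candidate ids.
#' @export
redundancy_screen <- function(candidates, hits, qlens, evalue_max = 1e-5,
                              min_qcov_pct = 30, min_identity_pct = 90) {
  if (nrow(hits) > 0 && !all(hits$query %in% candidates)) {
    stop("hit table refers to unknown candidate: ",
         setdiff(hits$query, candidates)[1])
  }
  if (nrow(hits) == 0L) return(candidates)
  ql <- qlens[hits$query]
  if (anyNA(ql)) stop("missing query length for: ",
                      hits$query[is.na(ql)][1])
  redundant <- hits$evalue <= evalue_max &
    100 * hits$aln_len / ql >= min_qcov_pct &
    hits$pct_identity > min_identity_pct
  setdiff(candidates, unique(hits$query[redundant]))
}

#' Polymorphism information content
#'
#' The Botstein measure for a single marker:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return PIC value in \[0, 1).
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  sp2 <- sum(p^2)
  sp4 <- sum(p^4)
  1 - sp2 - (sp2^2 - sp4)
}

#' Canonical form of a repeat unit
#'
#' Lexicographic minimum over all rotations of the unit and of its
#' reverse complement; used only by the optional canonical-grouping
#' report.
#'
#' @param unit character vector of repeat units.
#' @return canonical unit for each element.
#' @export
canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    rots <- function(s) vapply(seq_len(k), function(i) {
      paste0(substr(s, i, k), substr(s, 1L, i - 1L))
    }, "")
    min(c(rots(u), rots(revcomp(u))))
  }, "", USE.NAMES = FALSE)
}

#' Summarize an SSR search
#'
#' @param x sequence-set data.frame the motifs were mined from.
#' @param motifs motif data.frame (after [merge_compound()] if compound
#'   counts are wanted; a missing `compound` column counts as zero).
#' @return one-row data.frame: `n_sequences`, `total_bp`, `n_ssrs`,
#'   `n_sequences_with_ssr`, `n_sequences_with_multiple`, `n_compound`,
#'   `n_unit1` ... `n_unit6`.
#' @export
summarize_search <- function(x, motifs) {
  per_seq <- table(factor(motifs$tus_id, levels = x$id))
  per_unit <- tabulate(motifs$unit_len, nbins = 6L)
  out <- data.frame(
    n_sequences = nrow(x),
    total_bp = sum(nchar(x$seq)),
    n_ssrs = nrow(motifs),
    n_sequences_with_ssr = sum(per_seq >= 1L),
    n_sequences_with_multiple = sum(per_seq >= 2L),
    n_compound = if ("compound" %in% names(motifs)) sum(motifs$compound) else 0L)
  out[paste0("n_unit", 1:6)] <- as.list(per_unit)
  stopifnot(sum(per_unit) == out$n_ssrs)
  out
}

#' Write motifs as a MISA-compatible table
#'
#' Columns: ID, SSR nr, SSR type (p1..p6, marked c* when part of a
#' compound), SSR (motif)count, size, start, end.
#'
#' @param motifs motif data.frame (ideally after [merge_compound()]).
#' @param path output TSV.
#' @export
write_misa <- function(motifs, path) {
  nr <- stats::ave(seq_len(nrow(motifs)), motifs$tus_id, FUN = seq_along)
  type <- paste0("p", motifs$unit_len)
  if ("compound" %in% names(motifs)) type[motifs$compound] <-
      paste0("c*", type[motifs$compound])
  df <- data.frame(ID = motifs$tus_id, SSR_nr = nr, SSR_type = type,
                   SSR = paste0("(", motifs$unit, ")", motifs$repeat_count),
                   size = motifs$total_length, start = motifs$start,
                   end = motifs$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
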