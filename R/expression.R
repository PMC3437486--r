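# Tag-based digital expression: exact/1-mismatch mapping of fixed-length
# tags against a TUS set, per-million normalization, R-statistic
# differential-expression calls and DE-set accounting.

#' Build a tag-length k-mer index over a TUS set
#'
#' Every `tag_length`-mer of every TUS, on both strands, is retrievable
#' by exact hash. Two half-length seed tables support one-mismatch lookup
#' by the pigeonhole principle (a tag with one mismatch matches the
#' reference exactly on at least one half). TUSs shorter than
#' `tag_length` are skipped with a warning.
#'
#' @param tus sequence-set data.frame (`id`, `seq`).
#' @param tag_length tag length in nt (default 36).
#' @return an opaque index list used by [map_tags()].
#' @export
build_tag_index <- function(tus, tag_length = 36L) {
  half <- tag_length %/% 2L
  stopifnot(tag_length >= 2L * half, half >= 1L)
  len <- nchar(tus$seq)
  short <- len < tag_length
  if (any(short)) {
    warning(sum(short), " TUS(s) shorter than tag length ", tag_length,
            " skipped from the index")
  }
  pos_tus <- integer(0); pos_start <- integer(0); pos_strand <- character(0)
  kmers <- character(0)
  for (i in which(!short)) {
    L <- len[i]
    nk <- L - tag_length + 1L
    starts <- seq_len(nk)
    fwd <- substring(tus$seq[i], starts, starts + tag_length - 1L)
    rc <- revcomp(tus$seq[i])
    rev <- substring(rc, starts, starts + tag_length - 1L)
    # minus-strand k-mer at rc-position p covers TUS coords
    # (L - p - tag_length + 2) .. (L - p + 1)
    rev_start <- L - starts - tag_length + 2L
    pos_tus <- c(pos_tus, rep(i, 2L * nk))
    pos_start <- c(pos_start, starts, rev_start)
    pos_strand <- c(pos_strand, rep(c("+", "-"), each = nk))
    kmers <- c(kmers, fwd, rev)
  }
  exact <- list2env(split(seq_along(kmers), kmers), hash = TRUE)
  seed_left <- list2env(split(seq_along(kmers), substr(kmers, 1L, half)),
                        hash = TRUE)
  seed_right <- list2env(split(seq_along(kmers),
                               substr(kmers, half + 1L, tag_length)),
                         hash = TRUE)
  list(tus = tus, tag_length = tag_length, half = half,
       pos_tus = pos_tus, pos_start = pos_start, pos_strand = pos_strand,
       kmer = kmers, exact = exact,
       seed_left = seed_left, seed_right = seed_right)
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Map fixed-length tags against an indexed TUS set
#'
#' All equal-best placements are reported: zero-mismatch placements when
#' any exist, otherwise (if `max_mismatches = 1`) all one-mismatch
#' placements. Multimap policy is applied downstream by [count_tags()],
#' not here.
#'
#' @param tags character vector of tag sequences (length must equal the
#'   index tag length).
#' @param index from [build_tag_index()].
#' @param max_mismatches 0 or 1 (default 1).
#' @return data.frame with one row per placement: `tag` (input position),
#'   `tus_id`, `pos` (1-based leftmost TUS coordinate), `strand`,
#'   `mismatches`, `n_equal_best`.
#' @export
map_tags <- function(tags, index, max_mismatches = 1L) {
  stopifnot(max_mismatches %in% c(0L, 1L))
  if (length(tags) && any(nchar(tags) != index$tag_length)) {
    stop("all tags must have length ", index$tag_length)
  }
  uniq <- unique(tags)
  hits_for <- function(tag) {
    ix <- index$exact[[tag]]
    if (!is.null(ix)) return(list(ix = ix, mm = 0L))
    if (max_mismatches == 0L) return(NULL)
    lh <- index$seed_left[[substr(tag, 1L, index$half)]]
    rh <- index$seed_right[[substr(tag, index$half + 1L, index$tag_length)]]
    cand <- unique(c(lh, rh))
    if (is.null(cand)) return(NULL)
    mm <- vapply(index$kmer[cand], hamming, 0L, b = tag, USE.NAMES = FALSE)
    ok <- cand[mm == 1L]
    if (length(ok) == 0L) return(NULL)
    list(ix = ok, mm = 1L)
  }
  res <- lapply(uniq, hits_for)
  uix <- match(tags, uniq)
  nhit <- vapply(res, function(h) if (is.null(h)) 0L else length(h$ix), 0L)
  mm <- vapply(res, function(h) if (is.null(h)) NA_integer_ else h$mm, 0L)
  ixs <- lapply(res, function(h) h$ix)
  n_per_tag <- nhit[uix]
  all_ix <- unlist(ixs[uix], use.names = FALSE)
  out <- data.frame(
    tag = rep(seq_along(tags), n_per_tag),
    tus_id = index$tus$id[index$pos_tus[all_ix]],
    pos = index$pos_start[all_ix],
    strand = index$pos_strand[all_ix],
    mismatches = rep(mm[uix], n_per_tag),
    n_equal_best = rep(n_per_tag, n_per_tag),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate tag placements into per-TUS counts
#'
#' Policies: `unique_only` counts only tags with a single equal-best
#' placement (the default throughout, since heavy multi-mapping in an
#' EST assembly is usually assembler redundancy); `all` counts every
#' placement once; `fractional` counts each placement `1/n_equal_best`,
#' so fractional counts sum to the number of mapped tags.
#'
#' @param alignments from [map_tags()], one library.
#' @param multimap_policy `"unique_only"` (default), `"all"` or
#'   `"fractional"`.
#' @param tus_ids optional character vector fixing the output order (ids
#'   without placements get count 0).
#' @return data.frame `tus_id`, `count`.
#' @export
count_tags <- function(alignments,
                       multimap_policy = c("unique_only", "all", "fractional"),
                       tus_ids = NULL) {
  multimap_policy <- match.arg(multimap_policy)
  w <- switch(multimap_policy,
              unique_only = as.numeric(alignments$n_equal_best == 1L),
              all = rep(1, nrow(alignments)),
              fractional = 1 / alignments$n_equal_best)
  if (is.null(tus_ids)) tus_ids <- sort(unique(alignments$tus_id))
  counts <- tapply(w, factor(alignments$tus_id, levels = tus_ids), sum,
                   default = 0)
  data.frame(tus_id = tus_ids, count = as.numeric(counts),
             stringsAsFactors = FALSE)
}

#' R-statistic for two-library digital expression
#'
#' The log-likelihood-ratio statistic for differential representation of
#' one transcript between two tag libraries: with pooled rate
#' `f = (x1+x2)/(N1+N2)`, `R = sum_j x_j * ln(x_j / (N_j * f))` (natural
#' log; `0 * ln 0 = 0`). `R = 0` iff the two proportions are equal;
#' larger values mark stronger differential representation.
#'
#' @param x1,x2 tag counts (vectors allowed; no pair may be both zero).
#' @param N1,N2 library sizes (mapped tags).
#' @return nonnegative numeric vector.
#' @export
r_statistic <- function(x1, x2, N1, N2) {
  stopifnot(all(N1 > 0), all(N2 > 0), all(x1 >= 0), all(x2 >= 0))
  if (any(x1 == 0 & x2 == 0)) {
    stop("R-statistic undefined when both counts are zero")
  }
  f <- (x1 + x2) / (N1 + N2)
  term <- function(x, N) ifelse(x == 0, 0, x * log(x / (N * f)))
  pmax(term(x1, N1) + term(x2, N2), 0)
}

#' Expression category from raw counts
#'
#' @param x1,x2 tag counts.
#' @return `"both"`, `"exclusive_g1"`, `"exclusive_g2"` or
#'   `"undetected"`.
#' @export
classify_expression <- function(x1, x2) {
  ifelse(x1 > 0 & x2 > 0, "both",
         ifelse(x1 > 0, "exclusive_g1",
                ifelse(x2 > 0, "exclusive_g2", "undetected")))
}

#' Bin an absolute log2 fold change
#'
#' Bins on `|log2fc|`: `[0,1)` lt1, `[1,2)` b1_2, `[2,3)` b2_3, `[3,4]`
#' b3_4, and strictly greater than 4 gt4 ("more than four-fold" is a
#' strict bound, so the boundary value 4 falls in b3_4).
#'
#' @param log2fc numeric vector (defined values only).
#' @return character vector of bin labels.
#' @export
fold_bin <- function(log2fc) {
  a <- abs(log2fc)
  ifelse(a < 1, "lt1",
         ifelse(a < 2, "b1_2",
                ifelse(a < 3, "b2_3",
                       ifelse(a <= 4, "b3_4", "gt4"))))
}

#' Build the per-TUS expression table
#'
#' Computes counts-per-million (`x * 1e6 / N`, per million mapped tags of
#' each library), the log2 fold change `log2(cpm1/cpm2)` (defined only
#' when both counts are positive), the R-statistic (defined unless both
#' counts are zero), the expression category and the fold bin.
#'
#' @param counts1,counts2 data.frames from [count_tags()] on the same
#'   `tus_id` universe (same order).
#' @param N1,N2 library sizes; default = sum of the respective counts.
#' @return data.frame with one row per TUS and all expression fields.
#' @export
expression_table <- function(counts1, counts2, N1 = sum(counts1$count),
                             N2 = sum(counts2$count)) {
  stopifnot(identical(counts1$tus_id, counts2$tus_id))
  x1 <- counts1$count
  x2 <- counts2$count
  N1 <- rep_len(N1, length(x1))
  N2 <- rep_len(N2, length(x1))
  cpm1 <- x1 * 1e6 / N1
  cpm2 <- x2 * 1e6 / N2
  category <- classify_expression(x1, x2)
  log2fc <- ifelse(category == "both", log2(cpm1 / cpm2), NA_real_)
  R <- rep(NA_real_, length(x1))
  def <- x1 > 0 | x2 > 0
  if (any(def)) R[def] <- r_statistic(x1[def], x2[def], N1[def], N2[def])
  data.frame(tus_id = counts1$tus_id, x1 = x1, x2 = x2, N1 = N1, N2 = N2,
             cpm1 = cpm1, cpm2 = cpm2, log2fc = log2fc, R = R,
             category = category,
             fold_bin = ifelse(is.na(log2fc), "undefined", fold_bin(log2fc)),
             stringsAsFactors = FALSE)
}

#' Select the differential-expression set with accounting
#'
#' `DE = A union B` where `A = {|log2fc| >= min_abs_log2fc}` (among TUSs
#' expressed in both libraries) and `B = {R > r_threshold}`. The
#' accounting reports `|A|`, `|B|`, `|A intersect B|` and `|A union B|`
#' (inclusion-exclusion).
#'
#' @param tbl expression table from [expression_table()].
#' @param min_abs_log2fc minimum absolute log2 fold difference (default
#'   2, i.e. at least two units on the log2 expression scale).
#' @param r_threshold default 6.
#' @return list with `de` (tus_id vector), `n_fold`, `n_r`, `n_overlap`,
#'   `n_union`.
#' @export
select_de_set <- function(tbl, min_abs_log2fc = 2, r_threshold = 6) {
  A <- tbl$tus_id[!is.na(tbl$log2fc) & abs(tbl$log2fc) >= min_abs_log2fc]
  B <- tbl$tus_id[!is.na(tbl$R) & tbl$R > r_threshold]
  list(de = union(A, B), n_fold = length(A), n_r = length(B),
       n_overlap = length(intersect(A, B)),
       n_union = length(union(A, B)))
}

#' Union accounting from printed component sizes
#'
#' Pure inclusion-exclusion used by the report layer: given the size of
#' the fold-change set, of the R-statistic set and of their overlap,
#' returns the DE-set size `|A| + |B| - |A and B|`.
#'
#' @param n_fold,n_r,n_overlap component sizes.
#' @return the union size.
#' @export
de_union_size <- function(n_fold, n_r, n_overlap) {
  stopifnot(n_overlap <= n_fold, n_overlap <= n_r)
  n_fold + n_r - n_overlap
}
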