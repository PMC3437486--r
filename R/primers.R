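# Built-in primer picking engine.
#
# Thermodynamics: SantaLucia (1998) unified nearest-neighbor parameters,
# 50 mM monovalent salt with the entropic salt correction
# 0.368 * (N-1) * ln[Na+], 50 nM total oligo concentration (CT/4 term for
# non-self-complementary duplexes).

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' @param seq primer sequence(s), 5'->3', A/C/G/T only.
#' @param na_molar monovalent cation concentration (default 0.05 M).
#' @param oligo_molar total oligo concentration (default 5e-8 M, i.e.
#'   50 nM; the CT/4 convention for non-self-complementary duplexes).
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(seq, na_molar = 0.05, oligo_molar = 5e-8) {
  vapply(seq, function(s) {
    n <- nchar(s)
    stopifnot(n >= 2L)
    pairs <- substring(s, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    dh <- sum(NN_DH[pairs])
    ds <- sum(NN_DS[pairs])
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_molar)
    1000 * dh / (ds + 1.987 * log(oligo_molar / 4)) - 273.15
  }, 0, USE.NAMES = FALSE)
}

#' GC content in percent
#' @param seq character vector of DNA.
#' @return percent GC.
#' @export
gc_percent <- function(seq) {
  100 * (nchar(gsub("[^GC]", "", seq)) / nchar(seq))
}

#' Length of the longest homopolymer run
#' @param seq character vector of DNA.
#' @return integer vector.
#' @export
max_homopolymer <- function(seq) {
  vapply(seq, function(s) {
    max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
  }, 0L, USE.NAMES = FALSE)
}

#' Default primer-design parameters
#'
#' Mirrors common primer3-style defaults: length 18-27 (optimum 20), Tm
#' 57-63 C (optimum 60) by nearest-neighbor thermodynamics, pair Tm
#' difference at most 3 C, GC 30-70%, homopolymer runs at most 4 nt,
#' product size 100-500 bp.
#'
#' @param ... overrides for individual fields.
#' @return named list of parameters.
#' @export
primer_params <- function(...) {
  p <- list(primer_min = 18L, primer_max = 27L, opt_len = 20L,
            tm_min = 57, tm_max = 63, tm_opt = 60, max_tm_diff = 3,
            gc_min = 30, gc_max = 70, max_homopolymer = 4L,
            product_min = 100L, product_max = 500L, product_opt = NA_real_)
  over <- list(...)
  p[names(over)] <- over
  if (is.na(p$product_opt)) p$product_opt <- (p$product_min + p$product_max) / 2
  p
}

# All feasible single-primer candidates whose span lies within
# [win_start, win_end] of the template (template coordinates; right = TRUE
# yields reverse-complement primers). Returns start/end/len/seq/tm/gc.
#
# Under the unified nearest-neighbor table Tm, GC and homopolymer length
# are invariant under reverse complementation, so all windows are scored
# on the forward strand via cumulative sums; only the reported primer
# sequence is reverse-complemented.
primer_candidates <- function(template, win_start, win_end, params,
                              right = FALSE) {
  n <- nchar(template)
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  pair <- paste0(chars[-n], chars[-1])
  cum_dh <- c(0, cumsum(NN_DH[pair]))
  cum_ds <- c(0, cumsum(NN_DS[pair]))
  is_gc <- chars %in% c("G", "C")
  cum_gc <- c(0L, cumsum(is_gc))
  is_n <- chars == "N"
  cum_n <- c(0L, cumsum(is_n))
  # eqrun[p]: length of the equal-character run ending at p; a window
  # [s, e] contains a homopolymer longer than H iff some p in [s+H, e]
  # has eqrun[p] >= H + 1
  eqrun <- integer(n)
  eqrun[1] <- 1L
  for (p in seq_len(n)[-1]) {
    eqrun[p] <- if (chars[p] == chars[p - 1L]) eqrun[p - 1L] + 1L else 1L
  }
  hbad <- cumsum(eqrun >= params$max_homopolymer + 1L)
  salt_k <- 0.368 * log(0.05)
  conc_term <- 1.987 * log(5e-8 / 4)
  out <- list()
  for (len in params$primer_min:params$primer_max) {
    if (win_end - win_start + 1L < len) next
    starts <- seq.int(max(win_start, 1L), win_end - len + 1L)
    if (length(starts) == 0L) next
    ends <- starts + len - 1L
    ok <- cum_n[ends + 1L] - cum_n[starts] == 0L
    gc <- 100 * (cum_gc[ends + 1L] - cum_gc[starts]) / len
    ok <- ok & gc >= params$gc_min & gc <= params$gc_max
    lo <- pmin(starts + params$max_homopolymer - 1L, ends)
    ok <- ok & (hbad[ends] - hbad[lo]) == 0L
    if (!any(ok)) next
    dh <- cum_dh[ends] - cum_dh[starts] +
      ifelse(is_gc[starts], 0.1, 2.3) + ifelse(is_gc[ends], 0.1, 2.3)
    ds <- cum_ds[ends] - cum_ds[starts] +
      ifelse(is_gc[starts], -2.8, 4.1) + ifelse(is_gc[ends], -2.8, 4.1) +
      salt_k * (len - 1L)
    tm <- 1000 * dh / (ds + conc_term) - 273.15
    ok <- ok & tm >= params$tm_min & tm <= params$tm_max
    if (!any(ok)) next
    sub <- substring(template, starts[ok], ends[ok])
    out[[length(out) + 1L]] <- data.frame(
      start = starts[ok], end = ends[ok], len = len,
      seq = if (right) revcomp(sub) else sub,
      tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), len = integer(),
                      seq = character(), tm = numeric(), gc = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Deterministic best pair among feasible candidates: minimal
# |tm_left - 60| + |tm_right - 60|, then product size closest to the
# optimum, then leftmost (left start, then right start).
best_pair <- function(left, right, params) {
  if (nrow(left) == 0L) return(list(failure = "no_feasible_left"))
  if (nrow(right) == 0L) return(list(failure = "no_feasible_right"))
  best <- NULL
  dtm_r <- abs(right$tm - params$tm_opt)
  for (i in seq_len(nrow(left))) {
    prod <- right$end - left$start[i] + 1L
    ok <- which(prod >= params$product_min & prod <= params$product_max &
                  abs(right$tm - left$tm[i]) <= params$max_tm_diff &
                  right$start > left$end[i])
    if (length(ok) == 0L) next
    k1 <- abs(left$tm[i] - params$tm_opt) + dtm_r[ok]
    k2 <- abs(prod[ok] - params$product_opt)
    j <- ok[order(k1, k2, right$start[ok])[1]]
    key <- c(abs(left$tm[i] - params$tm_opt) + dtm_r[j],
             abs(prod[j] - params$product_opt),
             left$start[i], right$start[j])
    if (is.null(best) || compare_keys(key, best$key) < 0) {
      best <- list(i = i, j = j, key = key, product = prod[j])
    }
  }
  if (is.null(best)) return(list(failure = "no_feasible_pair"))
  best
}

compare_keys <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-9) return(-1L)
    if (a[k] > b[k] + 1e-9) return(1L)
  }
  0L
}

#' Pick the best primer pair around a target interval
#'
#' The left primer ends before the target start and the right primer
#' (reverse-complement orientation) begins after the target end. Among
#' all pairs meeting the constraints in `params`, the winner is chosen by
#' Tm proximity to the optimum, then product-size proximity to the
#' product optimum, then leftmost position -- fully deterministic.
#'
#' @param template template DNA string.
#' @param target_start,target_end 1-based inclusive target interval that
#'   the product must contain.
#' @param params from [primer_params()].
#' @return on success a one-row data.frame (`left_seq`, `right_seq`,
#'   `left_pos`, `right_pos` = 5' positions on the template, `tm_left`,
#'   `tm_right`, `gc_left`, `gc_right`, `product_size`); on failure an
#'   object of class `primer_failure` whose `"reason"` attribute is one
#'   of `no_feasible_left`, `no_feasible_right`, `no_feasible_pair`
#'   (test with [is_primer_failure()]).
#' @export
pick_primers <- function(template, target_start, target_end,
                         params = primer_params()) {
  n <- nchar(template)
  stopifnot(target_start >= 1L, target_end <= n, target_start <= target_end)
  left <- primer_candidates(template, 1L, target_start - 1L, params)
  right <- primer_candidates(template, target_end + 1L, n, params,
                             right = TRUE)
  b <- best_pair(left, right, params)
  if (!is.null(b$failure)) {
    return(primer_failure(b$failure))
  }
  data.frame(left_seq = left$seq[b$i], right_seq = right$seq[b$j],
             left_pos = left$start[b$i], right_pos = right$end[b$j],
             tm_left = left$tm[b$i], tm_right = right$tm[b$j],
             gc_left = left$gc[b$i], gc_right = right$gc[b$j],
             product_size = b$product, stringsAsFactors = FALSE)
}

primer_failure <- function(reason) {
  structure(list(), class = "primer_failure", reason = reason)
}

#' Did primer design fail?
#' @param x result of [pick_primers()] or [design_isr()] element.
#' @return `TRUE` for a failure object; its reason is
#'   `attr(x, "reason")`.
#' @export
is_primer_failure <- function(x) inherits(x, "primer_failure")
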