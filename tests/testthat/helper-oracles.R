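# Independent brute-force oracles used by the property tests. These are
# deliberately naive (direct enumeration, per-base counting) and share no
# code with the implementation paths they check.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Direct O(n^2 * 6) tandem-repeat enumeration: for every start and unit
# length, count unit repetitions by substring comparison; keep
# left-maximal candidates with primitive units meeting the thresholds;
# resolve overlaps left-to-right (longer tract first at equal start, then
# shorter unit).
oracle_find_ssrs <- function(seq, min_repeats = misa_min_repeats(),
                             tus_id = "seq") {
  n <- nchar(seq)
  cand <- list()
  for (k in 1:6) {
    for (s in seq_len(max(0L, n - k * min_repeats[k] + 1L))) {
      unit <- substr(seq, s, s + k - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      # primitive unit
      prim <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L && strrep(substr(unit, 1L, d), k / d) == unit) {
          prim <- FALSE
        }
      }
      if (!prim) next
      # left-maximality: no same-period match immediately before
      if (s > 1L && substr(seq, s - 1L, s - 1L) ==
            substr(seq, s + k - 1L, s + k - 1L)) next
      m <- 1L
      while (s + (m + 1L) * k - 1L <= n &&
               substr(seq, s + m * k, s + (m + 1L) * k - 1L) == unit) {
        m <- m + 1L
      }
      if (m < min_repeats[k]) next
      cand[[length(cand) + 1L]] <-
        list(start = s, end = s + m * k - 1L, unit = unit, k = k, m = m)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(tus_id = character(), start = integer(),
                      end = integer(), unit = character(),
                      unit_len = integer(), repeat_count = integer(),
                      total_length = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(cand, function(x) {
    data.frame(tus_id = tus_id, start = x$start, end = x$end,
               unit = x$unit, unit_len = x$k, repeat_count = x$m,
               total_length = x$m * x$k, stringsAsFactors = FALSE)
  }))
  df <- df[order(df$start, -df$total_length, df$unit_len), , drop = FALSE]
  keep <- logical(nrow(df))
  last_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive all-positions tag mapper: scan every window of every TUS on both
# strands and report all equal-best placements with <= max_mm mismatches.
oracle_map_tag <- function(tag, tus, max_mm = 1L) {
  L <- nchar(tag)
  hits <- list()
  for (i in seq_len(nrow(tus))) {
    s <- tus$seq[i]
    n <- nchar(s)
    if (n < L) next
    for (p in seq_len(n - L + 1L)) {
      win <- substr(s, p, p + L - 1L)
      mmf <- sum(utf8ToInt(win) != utf8ToInt(tag))
      if (mmf <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          tus_id = tus$id[i], pos = p, strand = "+", mismatches = mmf,
          stringsAsFactors = FALSE)
      }
      mmr <- sum(utf8ToInt(win) != utf8ToInt(revcomp(tag)))
      if (mmr <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          tus_id = tus$id[i], pos = p, strand = "-", mismatches = mmr,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, hits)
  df[df$mismatches == min(df$mismatches), , drop = FALSE]
}

# Per-base depth profile by direct counting.
oracle_depth_profile <- function(length, members) {
  depth <- integer(length)
  for (i in seq_len(nrow(members))) {
    for (p in members$start[i]:members$end[i]) depth[p] <- depth[p] + 1L
  }
  depth
}

# Transitive closure over pairwise adjacency (gap <= max_gap) for
# compound-SSR and transcribed-unit grouping checks.
oracle_transitive_groups <- function(start, end, max_gap) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(start[j], start[i]) - min(end[i], end[j]) - 1L
      overlap <- start[j] <= end[i] & start[i] <= end[j]
      adj[i, j] <- overlap | gap <= max_gap
    }
  }
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ])
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[adj[i, ]] <- g
    }
  }
  grp
}

# Exhaustive primer-pair search: enumerate every (start, length) window
# on each side, apply all constraints with scalar primer_tm(), and pick
# the best pair by the documented score.
oracle_pick_primers <- function(template, target_start, target_end,
                                params = primer_params()) {
  n <- nchar(template)
  singles <- function(lo, hi, right) {
    res <- list()
    for (len in params$primer_min:params$primer_max) {
      for (s in seq_len(n)) {
        e <- s + len - 1L
        if (s < lo || e > hi) next
        sq <- substr(template, s, e)
        if (right) sq <- revcomp(sq)
        gc <- gc_percent(sq)
        if (gc < params$gc_min || gc > params$gc_max) next
        if (max_homopolymer(sq) > params$max_homopolymer) next
        tm <- primer_tm(sq)
        if (tm < params$tm_min || tm > params$tm_max) next
        res[[length(res) + 1L]] <- data.frame(
          start = s, end = e, seq = sq, tm = tm, stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  left <- singles(1L, target_start - 1L, right = FALSE)
  right <- singles(target_end + 1L, n, right = TRUE)
  if (is.null(left) || is.null(right)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      prod <- right$end[j] - left$start[i] + 1L
      if (prod < params$product_min || prod > params$product_max) next
      if (abs(left$tm[i] - right$tm[j]) > params$max_tm_diff) next
      if (right$start[j] <= left$end[i]) next
      key <- c(abs(left$tm[i] - params$tm_opt) +
                 abs(right$tm[j] - params$tm_opt),
               abs(prod - params$product_opt), left$start[i],
               right$start[j])
      if (is.null(best) || keyless(key, best$key)) {
        best <- list(key = key, left = left[i, ], right = right[j, ],
                     product = prod)
      }
    }
  }
  best
}

keyless <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-9) return(TRUE)
    if (a[k] > b[k] + 1e-9) return(FALSE)
  }
  FALSE
}

# Small deterministic sequence set for mapper tests.
make_tus <- function(n, len, seed) {
  set.seed(seed)
  seq_set(sprintf("T%02d", seq_len(n)),
          vapply(rep(len, n), rand_dna, ""))
}
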