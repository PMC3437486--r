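# Post-assembly cleanup and TUS classification.
#
# Assembly itself is delegated to an external assembler (CAP3 preset
# "-p 95 -o 50 -g 3 -y 50 -t 1000" is the documented upstream
# configuration); this module consumes the assembler's contig FASTA plus a
# read-membership table.

#' Trim terminal poly-A / poly-T runs
#'
#' Removes a 3' poly-A run and a 5' poly-T run (the reverse-complement
#' artefact) of at least `min_run` nt, tolerating `max_mismatch_per10`
#' non-A (non-T) bases per 10 nt of run. Internal runs are untouched.
#' Trimming iterates to a fixed point, so it is idempotent by
#' construction.
#'
#' @param seq character vector of normalized DNA sequences.
#' @param min_run minimum terminal run length to trim (default 8).
#' @param max_mismatch_per10 mismatches tolerated per 10 nt of run
#'   (default 1).
#' @return character vector; an element trimmed to length zero is returned
#'   as `""` (callers decide whether to drop it).
#' @export
trim_polya <- function(seq, min_run = 8L, max_mismatch_per10 = 1L) {
  vapply(seq, function(s) {
    repeat {
      s2 <- trim_tail_run(s, base = "A", from_end = TRUE,
                          min_run = min_run,
                          max_mismatch_per10 = max_mismatch_per10)
      s2 <- trim_tail_run(s2, base = "T", from_end = FALSE,
                          min_run = min_run,
                          max_mismatch_per10 = max_mismatch_per10)
      if (identical(s2, s)) return(s2)
      s <- s2
    }
  }, "", USE.NAMES = FALSE)
}

# Maximal terminal run of `base`, where a non-base position is crossed only
# when the next 10 nt inward contain at most max_mismatch_per10 non-base
# characters (local density test); the run always ends on the base itself,
# so trailing mismatches are never trimmed. Trimmed only if >= min_run.
trim_tail_run <- function(s, base, from_end, min_run, max_mismatch_per10) {
  n <- nchar(s)
  if (n == 0L) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (from_end) chars <- rev(chars)
  run <- 0L
  i <- 1L
  while (i <= n) {
    if (chars[i] == base) {
      run <- i
    } else {
      win <- chars[seq.int(i + 1L, min(i + 10L, n))]
      if (i >= n || sum(win != base) > max_mismatch_per10) break
    }
    i <- i + 1L
  }
  if (run < min_run) return(s)
  if (run >= n) return("")
  if (from_end) substr(s, 1L, n - run) else substr(s, run + 1L, n)
}

#' Screen out low-complexity (homopolymer-dominated) sequences
#'
#' @param seq character vector of normalized DNA.
#' @param max_mono_fraction a sequence is dropped when any single base
#'   exceeds this fraction of its length (default 0.8).
#' @return logical vector, `TRUE` = keep.
#' @export
screen_low_complexity <- function(seq, max_mono_fraction = 0.8) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return(FALSE)
    counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                           levels = c("A", "C", "G", "T")))
    max(counts) / n <= max_mono_fraction
  }, NA, USE.NAMES = FALSE)
}

#' Read a contig membership table
#'
#' @param path TSV with columns contig_id, read_id, start, end (1-based
#'   inclusive placements on the contig).
#' @return data.frame.
#' @export
read_membership <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig_id", "read_id", "start", "end"),
                         colClasses = c("character", "character", "integer",
                                        "integer"), comment.char = "#")
  m
}

#' Classify one contig layout
#'
#' A two-read contig whose per-base depth profile is perfectly flat (zero
#' standard deviation, i.e. both reads span the full contig) is a
#' high-confidence singleton: informatically indistinguishable from a
#' singleton, it likely represents a unique gene expressed at low level.
#'
#' @param length contig length (nt).
#' @param members data.frame with columns `start`, `end` (1-based
#'   placements of member reads).
#' @return one of `"contig"`, `"singleton"`,
#'   `"high_confidence_singleton"`.
#' @export
classify_tus <- function(length, members) {
  if (nrow(members) < 1L) stop("contig layout must have at least one member")
  if (any(members$start < 1L | members$end > length |
          members$start > members$end)) {
    stop("read placement outside contig bounds [1, ", length, "]")
  }
  n <- nrow(members)
  if (n == 1L) return("singleton")
  if (n == 2L) {
    depth <- integer(length)
    for (i in seq_len(n)) {
      ix <- members$start[i]:members$end[i]
      depth[ix] <- depth[ix] + 1L
    }
    if (stats::sd(depth) == 0) return("high_confidence_singleton")
  }
  "contig"
}

#' Classify every contig in a membership table
#'
#' @param lengths named integer vector of contig lengths.
#' @param membership data.frame from [read_membership()].
#' @return data.frame with columns `tus_id`, `n_members`, `tus_class`.
#' @export
classify_tus_set <- function(lengths, membership) {
  ids <- names(lengths)
  cls <- character(length(ids))
  nm <- integer(length(ids))
  by_contig <- split(membership, membership$contig_id)
  for (i in seq_along(ids)) {
    mem <- by_contig[[ids[i]]]
    if (is.null(mem)) stop("contig without members: ", ids[i])
    cls[i] <- classify_tus(lengths[[i]], mem)
    nm[i] <- nrow(mem)
  }
  data.frame(tus_id = ids, n_members = nm, tus_class = cls,
             stringsAsFactors = FALSE)
}

#' Read-length histogram
#'
#' Bins are `[1..w]`, `[w+1..2w]`, ...; counts always sum to the number of
#' input sequences.
#'
#' @param lengths integer vector of sequence lengths.
#' @param bin_width bin width in nt (default 50).
#' @return data.frame with `bin_start`, `bin_end`, `count` (empty bins up
#'   to the maximum length included).
#' @export
length_histogram <- function(lengths, bin_width = 50L) {
  stopifnot(bin_width > 0)
  if (length(lengths) == 0L) {
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  bin <- (lengths - 1L) %/% bin_width
  nbin <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nbin)
  data.frame(bin_start = (seq_len(nbin) - 1L) * bin_width + 1L,
             bin_end = seq_len(nbin) * bin_width,
             count = counts)
}
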