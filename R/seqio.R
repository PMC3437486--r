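# Sequence sets are plain data.frames with columns id, desc, seq.
# One coordinate convention everywhere: 1-based, inclusive.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Assemble a sequence-set data frame
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of DNA sequences (A/C/G/T/N after
#'   normalization).
#' @param desc optional free-text descriptions.
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
seq_set <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  }
  data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
             seq = normalize_dna(seq), stringsAsFactors = FALSE)
}

#' Normalize DNA residues
#'
#' Upper-cases, maps U to T, and rejects any character outside A/C/G/T/N.
#' Ambiguity codes beyond N are rejected rather than remapped: the repeat
#' and k-mer machinery downstream assumes a five-letter alphabet.
#'
#' @param seq character vector.
#' @return normalized character vector.
#' @export
normalize_dna <- function(seq) {
  out <- chartr("u", "T", chartr("U", "T", toupper(seq)))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1], regexpr("[^ACGTN]", out[bad][1]))
    stop("sequence contains character outside the A/C/G/T/N alphabet: '",
         ch, "'")
  }
  out
}

#' Read a FASTA file into a sequence set
#'
#' Records are returned in file order; residues are normalized (upper case,
#' U mapped to T); duplicate identifiers, malformed headers and empty files
#' are rejected with distinct errors.
#'
#' @param path FASTA file (gzip accepted).
#' @return sequence-set data.frame (`id`, `desc`, `seq`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA header in ", path, ": first line does not start with '>'")
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  if (any(!nzchar(id))) stop("malformed FASTA header: empty id")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id in ", path, ": ", id[duplicated(id)][1])
  }
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  data.frame(id = id, desc = desc, seq = normalize_dna(as.character(x)),
             stringsAsFactors = FALSE)
}

#' Write a sequence set as FASTA
#'
#' @param x sequence-set data.frame.
#' @param path output file.
#' @param width line width for wrapping (default 70).
#' @export
write_fasta <- function(x, path, width = 70L) {
  hdr <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  dna <- Biostrings::DNAStringSet(x$seq)
  names(dna) <- hdr
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Sanger +33 qualities)
#'
#' Qualities are parsed but carried along unused: tag libraries are assumed
#' quality-filtered upstream.
#'
#' @param path FASTQ file (gzip accepted).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", unname(names(x))),
             seq = unname(normalize_dna(as.character(x))),
             qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file (Sanger +33 qualities)
#'
#' @param x data.frame with `id`, `seq` and optionally `qual` (defaults to
#'   maximum-confidence 'I').
#' @param path output file.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("qual" %in% names(x)) x$qual else
    vapply(nchar(x$seq), function(n) strrep("I", n), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read a 12-column tabular similarity hit file
#'
#' The standard BLAST-style tabular layout: query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore. Comment lines (leading `#`) are skipped; any
#' line with a wrong column count or a non-numeric numeric field raises a
#' parse error naming the line.
#'
#' @param path tab-separated hit file.
#' @return data.frame with typed columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  cols <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  if (!any(keep)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != 12L)) {
    lineno <- which(keep)[which(nfld != 12L)[1]]
    stop("hit table parse error at line ", lineno, " of ", path, ": found ",
         nfld[nfld != 12L][1], " columns, expected 12")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad_row <- which(rowSums(is.na(num)) > 0)[1]
    lineno <- which(keep)[bad_row]
    stop("hit table parse error at line ", lineno, " of ", path,
         ": non-numeric value in a numeric field")
  }
  out <- data.frame(query = m[, 1], subject = m[, 2], stringsAsFactors = FALSE)
  out[cols[3:12]] <- as.data.frame(num)
  if (any(out$qstart > out$qend)) stop("hit table invariant violated: qstart > qend")
  if (any(out$evalue < 0)) stop("hit table invariant violated: negative evalue")
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("hit table invariant violated: pct_identity outside [0,100]")
  }
  out
}

#' Write a 12-column tabular hit file
#' @param hits data.frame as returned by [read_hit_table()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse-complement DNA strings
#' @param seq character vector over A/C/G/T/N.
#' @return reverse complement of each element.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
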