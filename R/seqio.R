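#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than `N` is
#' mapped to `N` (with a warning), so downstream code only ever sees the
#' alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited token of the header), `desc` (remainder of the
#'   header, `""` if absent) and `seq`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) {
    stop("no sequence records found in '", path, "'")
  }
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    warning("duplicate sequence ids in '", path, "': ",
            paste(unique(id[duplicated(id)]), collapse = ", "),
            " (all records kept)")
  }
  seq <- clean_residues(toupper(as.character(x)))
  if (any(nchar(seq) == 0L)) {
    stop("zero-length sequence record(s) in '", path, "'")
  }
  tibble::tibble(id = id, desc = desc, seq = unname(seq))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- fasta_headers(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

fasta_headers <- function(seqs) {
  desc <- if ("desc" %in% names(seqs)) seqs$desc else ""
  ifelse(is.na(desc) | desc == "", seqs$id, paste(seqs$id, desc))
}

# Uppercase input assumed; maps ambiguity codes other than N to N.
clean_residues <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained ambiguity codes other than N; ",
            "mapped to N")
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  seq
}

#' Read a 4-line-record FASTQ file into a read tibble
#'
#' The file is validated before parsing: each record must consist of an
#' `@header`, a sequence line, a `+` separator and a quality line of the same
#' length as the sequence. A mismatch is reported with the offending record's
#' id.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `id`, `desc`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0L) stop("no FASTQ records found in '", path, "'")
  if (length(lines) %% 4L != 0L) {
    stop("'", path, "' does not consist of 4-line FASTQ records")
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  sep <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(sep, "+"))) {
    stop("malformed FASTQ record structure in '", path, "'")
  }
  len_mismatch <- nchar(seq) != nchar(qual)
  if (any(len_mismatch)) {
    bad <- sub("^@", "", hdr[which(len_mismatch)[1L]])
    stop("sequence/quality length mismatch in record '",
         sub("\\s.*$", "", bad), "' of '", path, "'")
  }
  headers <- sub("^@", "", hdr)
  tibble::tibble(
    id = sub("\\s.*$", "", headers),
    desc = ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), ""),
    seq = clean_residues(toupper(seq)),
    qual = qual
  )
}

#' Write a read tibble to 4-line FASTQ
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` and optionally `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  out <- rbind(paste0("@", fasta_headers(reads)), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Trim reads at runs of 'B' quality symbols
#'
#' Applies the Illumina 1.3–1.5 "B-tail" rule: if a read's quality string
#' contains a run of five or more consecutive `B` symbols, the read is
#' truncated immediately before the first base of the first such run (that
#' run and everything 3' of it is discarded). Reads left with zero bases are
#' dropped from the result. Matching is on the literal character `B`, not on
#' a phred threshold.
#'
#' @param reads Read tibble as returned by [read_fastq()].
#' @param min_run Minimum run length that triggers trimming (default 5).
#' @return The trimmed read tibble; fully-low-quality reads are removed.
#' @export
trim_reads <- function(reads, min_run = 5L) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  pat <- paste0("B{", min_run, "}")
  cut <- regexpr(pat, reads$qual)
  keep_len <- ifelse(cut == -1L, nchar(reads$seq), cut - 1L)
  out <- reads
  out$seq <- substr(out$seq, 1L, keep_len)
  out$qual <- substr(out$qual, 1L, keep_len)
  out[keep_len > 0L, , drop = FALSE]
}

hit_table_cols <- c(
  "query_id", "subject_id", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a 12-column tabular hit table
#'
#' Parses the standard 12-column tab-separated local-alignment hit layout
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, E-value, bit score). Query and
#' subject coordinates are kept as parsed: 1-based and inclusive.
#'
#' @param path Path to the tab-separated file. An empty file yields an empty
#'   tibble.
#' @return A tibble with columns
#'   `query_id, subject_id, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore`.
#' @export
read_hit_table <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(empty_hit_table())
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns but found ", nf[nf != 12L][1L],
         " on line ", which(nf != 12L)[1L], " of '", path, "'")
  }
  readr::read_tsv(
    path,
    col_names = hit_table_cols,
    col_types = readr::cols(
      query_id = "c", subject_id = "c", pident = "d", length = "i",
      mismatch = "i", gapopen = "i", qstart = "i", qend = "i",
      sstart = "i", send = "i", evalue = "d", bitscore = "d"
    ),
    progress = FALSE
  )
}

empty_hit_table <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), pident = double(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = double(), bitscore = double()
  )
}

#' Write a hit tibble as a 12-column tabular file
#'
#' E-values are written in scientific notation with full precision so that
#' [read_hit_table()] round-trips losslessly.
#'
#' @param hits Hit tibble (see [read_hit_table()] for the columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_table_cols %in% names(hits)))
  out <- hits[hit_table_cols]
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
    out$query_id, out$subject_id,
    format(out$pident, trim = TRUE, digits = 15),
    out$length, out$mismatch, out$gapopen,
    out$qstart, out$qend, out$sstart, out$send,
    format(out$evalue, trim = TRUE, scientific = TRUE, digits = 15),
    format(out$bitscore, trim = TRUE, digits = 15)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param seq Character vector over `A,C,G,T,N`.
#' @return Reverse complements as a character vector.
#' @export
revcomp <- function(seq) {
  vapply(
    seq,
    function(s) {
      chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
    },
    character(1L),
    USE.NAMES = FALSE
  )
}
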