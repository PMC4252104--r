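#' Read paired-end FASTQ
#'
#' Reads two mate files, or one interleaved file, into a read-pair table.
#' Mates are kept 5'->3' as sequenced (forward-reverse libraries point the
#' two ends of a pair toward each other).  N bases are preserved; k-mers
#' spanning them are simply never indexed.
#'
#' @param path1 FASTQ file with first mates, or an interleaved file.
#' @param path2 FASTQ file with second mates, or `NULL` for interleaved
#'   input.
#' @return A `data.frame` with columns `id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`, one row per pair, ids numbered consecutively from 1.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@p1/1", "ACGT", "+", "IIII", "@p1/2", "TTGG", "+", "IIII"),
#'            fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path1, path2 = NULL) {
  if (is.null(path2)) {
    all <- parse_fastq_file(path1)
    if (nrow(all) %% 2L != 0L)
      stop("interleaved FASTQ '", path1, "' has an odd number of records")
    odd <- seq(1L, nrow(all), by = 2L)
    out <- data.frame(id = seq_along(odd),
                      seq1 = all$seq[odd], seq2 = all$seq[odd + 1L],
                      qual1 = all$qual[odd], qual2 = all$qual[odd + 1L],
                      stringsAsFactors = FALSE)
    return(out)
  }
  r1 <- parse_fastq_file(path1)
  r2 <- parse_fastq_file(path2)
  if (nrow(r1) != nrow(r2)) {
    shorter <- if (nrow(r1) < nrow(r2)) path1 else path2
    stop("mate files differ in record count (", nrow(r1), " vs ", nrow(r2),
         "); '", shorter, "' is shorter")
  }
  data.frame(id = seq_len(nrow(r1)),
             seq1 = r1$seq, seq2 = r2$seq,
             qual1 = r1$qual, qual2 = r2$qual,
             stringsAsFactors = FALSE)
}

parse_fastq_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (record ",
         length(lines) %/% 4L + 1L, ")")
  ix <- seq(1L, length(lines), by = 4L)
  bad <- which(substr(lines[ix], 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " does not start with '@'")
  seqs <- toupper(lines[ix + 1L])
  quals <- lines[ix + 3L]
  badlen <- which(nchar(seqs) != nchar(quals))
  if (length(badlen))
    stop("malformed FASTQ '", path, "': record ", badlen[1L],
         " sequence/quality length mismatch")
  data.frame(seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write paired-end FASTQ
#'
#' @param pairs read-pair table as returned by [read_fastq()] or
#'   [simulate_pairs()].
#' @param path1,path2 output mate files.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(pairs, path1, path2) {
  q1 <- pairs$qual1
  if (is.null(q1)) q1 <- strrep("I", nchar(pairs$seq1))
  q2 <- pairs$qual2
  if (is.null(q2)) q2 <- strrep("I", nchar(pairs$seq2))
  writeLines(as.vector(rbind(paste0("@pair", pairs$id, "/1"),
                             pairs$seq1, "+", q1)), path1)
  writeLines(as.vector(rbind(paste0("@pair", pairs$id, "/2"),
                             pairs$seq2, "+", q2)), path2)
  invisible(c(path1, path2))
}

#' Write sequences as FASTA
#'
#' @param records named character vector of sequences (names become
#'   headers), or a list of `(name, sequence)` pairs.
#' @param path output file.
#' @param wrap line width for the sequence lines.
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' write_fasta(c(c1 = "ACGT"), f)
#' readLines(f)
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.list(records) && !is.null(records[[1]]) && length(records) &&
      is.null(names(records)))
    records <- setNames(vapply(records, `[[`, "", 2L),
                        vapply(records, `[[`, "", 1L))
  records <- unlist(records)
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must have unique names")
  x <- Biostrings::DNAStringSet(unname(records))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of (uppercase) sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
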