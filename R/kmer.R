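#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographic minimum of a k-mer and its
#' reverse complement, so that both strands of the same sequence hash to
#' the same index entry.
#'
#' @param kmer DNA string over A/C/G/T, at most 31 bp.
#' @return The canonical k-mer.
#' @examples
#' canonical_kmer("CGT")   # "ACG"
#' canonical_kmer("ACGT")  # palindromic under reverse complement
#' @export
canonical_kmer <- function(kmer) {
  vapply(as.character(kmer), cpp_canonical, "", USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  vapply(as.character(x), cpp_revcomp, "", USE.NAMES = FALSE)
}

#' Build the k-mer occurrence index over a read set
#'
#' Every sampled k-mer of every read is stored, keyed by its canonical
#' form, as an ordered occurrence list (read, mate, position, strand).
#' Two reads that overlap error-free over w bases share w - k + 1
#' consecutive k-mers, which is what makes the index an overlap oracle:
#' read-to-contig alignment only ever needs a hash lookup of the contig's
#' terminal k-mer followed by direct sequence comparison.
#'
#' With `sample_fraction` f < 1 only the ceil(f/2 * (L-k+1)) k-mer start
#' positions closest to each read end are indexed (the paper's
#' ten-percent-at-both-ends memory-saving rule at f = 0.1); reads are then
#' recruited when the growing contig end passes over one of their
#' end-anchored k-mers.
#'
#' @param reads read-pair table (columns `seq1`, `seq2`) from
#'   [read_fastq()] or [simulate_pairs()], or a list with element `pairs`.
#' @param cfg an [assembly_config()].
#' @return An object of class `kmer_index` wrapping the in-memory table.
#' @examples
#' reads <- data.frame(id = 1, seq1 = "ACGTACGT", seq2 = "AAAATTTT")
#' idx <- build_kmer_index(reads, assembly_config(k = 3, O_max = 5,
#'                                                sample_fraction = 1))
#' kmer_lookup(idx, "ACG")
#' @export
build_kmer_index <- function(reads, cfg = assembly_config()) {
  reads <- as_pairs(reads)
  if (nrow(reads) == 0L) stop("no reads to index")
  minlen <- min(nchar(c(reads$seq1, reads$seq2)))
  if (cfg$k > minlen)
    stop("k = ", cfg$k, " exceeds the shortest read length (", minlen, ")")
  ptr <- idx_build(reads$seq1, reads$seq2, cfg$k, cfg$sample_fraction)
  structure(list(ptr = ptr, k = cfg$k,
                 sample_fraction = cfg$sample_fraction,
                 n_pairs = nrow(reads), reads = reads),
            class = "kmer_index")
}

as_pairs <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$pairs))
    reads <- reads$pairs
  stopifnot(is.data.frame(reads), all(c("seq1", "seq2") %in% names(reads)))
  reads
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- idx_info(x$ptr)
  cat("kmer_index: k =", info$k, " pairs =", info$n_pairs,
      " keys =", info$n_keys, " occurrences =", info$n_occurrences, "\n")
  invisible(x)
}

#' Occurrence list of a k-mer
#'
#' @param index a `kmer_index`.
#' @param kmer query k-mer (either strand).
#' @return `data.frame` with columns `read_id`, `mate`, `pos` (0-based
#'   k-mer start on the read as sequenced) and `strand` (`"+"` when the
#'   read's own k-mer equals the canonical key), sorted ascending by
#'   (read, mate, pos).
#' @export
kmer_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  idx_lookup(index$ptr, as.character(kmer))
}

#' Total sampled occurrence count of a k-mer (and its reverse complement)
#'
#' @inheritParams kmer_lookup
#' @return Integer count; 0 for unseen or non-ACGT k-mers.
#' @export
kmer_freq <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  vapply(as.character(kmer), function(s) idx_freq(index$ptr, s), 1L,
         USE.NAMES = FALSE)
}

#' Longest run of consecutive shared k-mers between two reads
#'
#' If two reads overlap error-free over exactly w >= k bases, the run has
#' length w - k + 1; the function scans every alignment diagonal and is
#' therefore robust to where the overlap sits.
#'
#' @param readA,readB DNA strings.
#' @param k k-mer size.
#' @return Integer; 0 when no k-mer is shared.
#' @examples
#' shared_consecutive_kmers("ACGTACGTAC", "GTACGTACGA", 3)  # w = 8 -> 6
#' @export
shared_consecutive_kmers <- function(readA, readB, k) {
  cpp_shared_consecutive(as.character(readA), as.character(readB),
                         as.integer(k))
}
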