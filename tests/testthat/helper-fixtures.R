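# Shared fixtures, built in code at test time.

BASES <- c("A", "C", "G", "T")

rnd_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# small configuration used by most engine-level tests: every k-mer indexed
test_cfg <- function(...) {
  args <- list(k = 15L, O_max = 40L, sample_fraction = 1,
               navigation = "heuristic", min_insert_n = 5L,
               linking_region = 500L)
  args[names(list(...))] <- list(...)
  do.call(assembly_config, args)
}

# a tiny error-free simulation shared by several tests
small_sim <- function(G = 8000L, coverage = 40, err = 0, seed = 5L,
                      repeats = list()) {
  g <- generate_genome(G, repeats, seed = seed)
  sim <- simulate_pairs(g, coverage = coverage, err_rate = err, seed = seed)
  list(genome = g, sim = sim)
}

# plant an exact duplication: copy `len` bases from `from` to `to`
plant_dup <- function(G, from, len, to) {
  substr(G, to, to + len - 1L) <- substr(G, from, from + len - 1L)
  G
}

# manufacture a read_pools-like object for tally/feature tests without an
# engine run
fake_pools <- function(pool1, pool2 = NULL, support = rep(1L, 100L),
                       insert = list(mean = 0, sd = 0, n = 0L),
                       read_len = 100L) {
  if (is.null(pool2))
    pool2 <- data.frame(read_id = integer(0), mate = integer(0),
                        off = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  p <- structure(list(pool1 = pool1, pool2 = pool2, support = support,
                      insert = insert), class = "read_pools")
  attr(p, "read_len") <- read_len
  p
}

fake_pool1 <- function(bases, overlap = 30L, paired = FALSE,
                       strand = NULL) {
  n <- length(bases)
  if (is.null(strand)) strand <- ifelse(rep(paired, length.out = n),
                                        "-", "+")
  data.frame(read_id = seq_len(n) + 1000L,
             mate = rep(1L, n), off = rep(0L, n),
             strand = rep(strand, length.out = n),
             overlap = rep(overlap, length.out = n),
             next_base = bases,
             paired_support = rep(paired, length.out = n),
             stringsAsFactors = FALSE)
}

# a candidate_path-like object for look-ahead logic tests
fake_path <- function(seq, reads = NULL, mm = 0L, pair_d = numeric(0),
                      died_early = FALSE) {
  if (is.null(reads))
    reads <- data.frame(read_id = integer(0), off = integer(0),
                        seq = character(0), stringsAsFactors = FALSE)
  structure(list(seq = seq, first_base = substr(seq, 1, 1), reads = reads,
                 mismatches_vs_contig = mm, died_early = died_early,
                 pair_distances = pair_d),
            class = "candidate_path")
}

# reads supporting a given path sequence: tiled substrings, offsets
# relative to the branch (may reach back into the contig via `back`)
path_reads <- function(contig_tail, path_seq, n = 6L, read_len = 30L) {
  full <- paste0(contig_tail, path_seq)
  back <- nchar(contig_tail)
  offs <- floor(seq(0, max(0, nchar(full) - read_len), length.out = n))
  data.frame(read_id = seq_len(n), off = offs - back,
             seq = substring(full, offs + 1L, offs + read_len),
             stringsAsFactors = FALSE)
}
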