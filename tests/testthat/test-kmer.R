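test_that("canonical form is the lexicographic minimum of both strands", {
  expect_equal(canonical_kmer("ACG"), "ACG")
  expect_equal(canonical_kmer("CGT"), "ACG")  # revcomp of ACG
  expect_equal(canonical_kmer("ACGT"), "ACGT")  # its own reverse complement
  expect_error(canonical_kmer("ACN"), "non-ACGT")
})

test_that("canonical(s) equals canonical(revcomp(s)) for random k-mers", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(3:31, 1)
    s <- rnd_dna(k)
    expect_equal(canonical_kmer(s), canonical_kmer(revcomp_dna(s)))
    expect_true(canonical_kmer(s) %in% c(s, revcomp_dna(s)))
    expect_true(canonical_kmer(s) <= s)
  }
})

test_that("full index enumerates every k-mer position of a read", {
  reads <- data.frame(id = 1L, seq1 = "ACGTACGT", seq2 = "AAAAAAAA",
                      stringsAsFactors = FALSE)
  cfg <- assembly_config(k = 3, O_max = 5, sample_fraction = 1)
  idx <- build_kmer_index(reads, cfg)
  # mate 1 has 6 k-mer start positions in total
  info <- idx_info(idx$ptr)
  expect_equal(info$n_occurrences, 6 + 6)  # both mates fully sampled
  occ <- kmer_lookup(idx, "ACG")
  m1 <- occ[occ$mate == 1L, ]
  # forward hits of ACG at 0 and 4; CGT (same canonical entry) at 1 and 5
  expect_equal(sort(m1$pos[m1$strand == "+"]), c(0L, 4L))
  expect_equal(sort(m1$pos), c(0L, 1L, 4L, 5L))
  # occurrence lists are sorted ascending by (read, mate, pos)
  expect_false(is.unsorted(occ$pos[occ$mate == 1L]))
})

test_that("a read and its reverse complement index to identical keys", {
  s <- rnd_dna(40)
  cfg <- assembly_config(k = 11, O_max = 20, sample_fraction = 1)
  i1 <- build_kmer_index(data.frame(id = 1, seq1 = s, seq2 = s), cfg)
  i2 <- build_kmer_index(data.frame(id = 1, seq1 = revcomp_dna(s),
                                    seq2 = s), cfg)
  expect_equal(idx_info(i1$ptr)$n_keys, idx_info(i2$ptr)$n_keys)
  # spot check: every sampled k-mer of the read is findable
  for (p in c(0, 10, 29)) {
    km <- substr(s, p + 1, p + 11)
    expect_gte(nrow(kmer_lookup(i1, km)), 1L)
    expect_gte(nrow(kmer_lookup(i2, km)), 1L)
  }
})

test_that("end sampling indexes at most ceil(f/2 (L-k+1)) per read end", {
  set.seed(2)
  reads <- data.frame(id = 1:5,
                      seq1 = replicate(5, rnd_dna(100)),
                      seq2 = replicate(5, rnd_dna(100)),
                      stringsAsFactors = FALSE)
  cfg <- assembly_config(k = 25, O_max = 70, sample_fraction = 0.1)
  idx <- build_kmer_index(reads, cfg)
  info <- idx_info(idx$ptr)
  # ceil(0.05 * 76) = 4 positions per end, both ends, both mates
  expect_lte(info$n_occurrences, 5 * 2 * 8)
  # the sampled positions hug the read ends
  occ <- kmer_lookup(idx, substr(reads$seq1[1], 1, 25))
  expect_true(any(occ$pos == 0))
})

test_that("N-containing k-mers are never indexed", {
  reads <- data.frame(id = 1, seq1 = "ACGTNACGTACG", seq2 = "ACGTACGTACGT")
  cfg <- assembly_config(k = 5, O_max = 8, sample_fraction = 1)
  idx <- build_kmer_index(reads, cfg)
  occ <- kmer_lookup(idx, "ACGTA")
  expect_true(all(occ$pos[occ$mate == 1L] > 4L))  # spans over N skipped
})

test_that("consecutive shared k-mers equal w - k + 1 for planted overlaps", {
  # worked example: 8 bp overlap with k = 3 shares 6 consecutive k-mers
  expect_equal(shared_consecutive_kmers("ACGTACGTAC", "GTACGTACGA", 3), 6L)
  # boundaries
  s <- rnd_dna(30)
  expect_equal(shared_consecutive_kmers(s, s, 7), 30 - 7 + 1)
  set.seed(3)
  for (i in 1:40) {
    k <- sample(3:15, 1)
    L <- sample(30:60, 1)
    w <- sample(k:(L - 1), 1)
    a <- rnd_dna(L)
    b <- paste0(substr(a, L - w + 1, L), rnd_dna(L - w))  # planted overlap
    got <- shared_consecutive_kmers(a, b, k)
    expect_gte(got, w - k + 1)  # chance matches can only lengthen a run
  }
  expect_equal(shared_consecutive_kmers("AAAA", "CCCC", 3), 0L)
})

test_that("k-mer frequency counts all sampled occurrences of both strands", {
  reads <- data.frame(id = 1:3, seq1 = rep("ACGTACGT", 3),
                      seq2 = rep("TTTTTTTT", 3))
  cfg <- assembly_config(k = 3, O_max = 5, sample_fraction = 1)
  idx <- build_kmer_index(reads, cfg)
  expect_equal(kmer_freq(idx, "ACG"), kmer_freq(idx, "CGT"))
  expect_equal(kmer_freq(idx, "ACG"), 12L)  # 4 per mate-1 read
})
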