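cfg15 <- test_cfg()

test_that("contig seeding skips used reads and low-frequency start k-mers", {
  set.seed(10)
  s <- rnd_dna(50)
  reads <- data.frame(id = 1:6,
                      seq1 = c(rnd_dna(50), rep(s, 5)),
                      seq2 = replicate(6, rnd_dna(50)),
                      stringsAsFactors = FALSE)
  idx <- build_kmer_index(reads, cfg15)
  sd1 <- seed_contig(idx, used = integer(0), cfg = cfg15)
  # read 1's terminal k-mer occurs once (like a sequencing error): skipped
  expect_equal(sd1$read_id, 2L)
  expect_equal(sd1$seq, substr(s, 1, 15))
  expect_null(seed_contig(idx, used = 1:6, cfg = cfg15))
})

test_that("read alignment builds the pools and rejects foreign reads", {
  set.seed(11)
  contig <- rnd_dna(600)
  readA <- paste0(substr(contig, 561, 600), rnd_dna(60))     # 40 bp overlap
  readB <- substr(contig, 200, 299)                          # contained
  readC <- paste0(rnd_dna(40), substr(contig, 586, 600), rnd_dna(45))
  reads <- data.frame(id = 1:3, seq1 = c(readA, readB, readC),
                      seq2 = replicate(3, rnd_dna(100)),
                      stringsAsFactors = FALSE)
  idx <- build_kmer_index(reads, cfg15)
  pools <- align_candidates(contig, idx, cfg15)
  # read A: partial at the 3' end, candidate base = first overhang base
  a <- pools$pool1[pools$pool1$read_id == 1L & pools$pool1$mate == 1L, ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$overlap, 40L)
  expect_equal(a$next_base, substr(readA, 41, 41))
  # read B: fully aligned, lands in pool 2
  expect_true(2L %in% pools$pool2$read_id)
  # read C shares only a 15 bp island over a 55 bp span (< 90% matching):
  # kept available for other regions, in neither pool
  expect_false(3L %in% c(pools$pool1$read_id, pools$pool2$read_id))
})

test_that("tallies honour paired support and the overlap threshold", {
  # paired mode: C backed by mates in pool 2, T has no paired support
  p1 <- rbind(fake_pool1(rep("C", 3), paired = TRUE),
              fake_pool1(rep("T", 2), paired = FALSE))
  pools <- fake_pools(p1)
  expect_equal(tally_candidates(pools, "paired"),
               c(A = 0L, C = 3L, G = 0L, T = 0L))
  # variable overlap: at O = 6 only the two long-overlap reads qualify
  p2 <- rbind(fake_pool1(rep("G", 2), overlap = c(6L, 7L)),
              fake_pool1(rep("T", 2), overlap = c(4L, 4L)))
  pools2 <- fake_pools(p2)
  expect_equal(tally_candidates(pools2, "single", O = 6L)[["G"]], 2L)
  expect_equal(sum(tally_candidates(pools2, "single", O = 6L)), 2L)
  expect_equal(sum(tally_candidates(pools2, "single", O = 4L)), 4L)
  # empty pools: all-zero tally
  empty <- fake_pools(fake_pool1(character(0)))
  expect_equal(sum(tally_candidates(empty, "paired")), 0L)
})

test_that("reads eligible at overlap O nest monotonically in O", {
  fx <- small_sim(G = 4000, coverage = 30, seed = 12)
  idx <- build_kmer_index(fx$sim$pairs, cfg15)
  contig <- substr(fx$genome$seq, 1001, 1600)
  pools <- align_candidates(contig, idx, cfg15)
  sums <- vapply(15:40, function(O)
    sum(tally_candidates(pools, "single", O)), 1L)
  expect_true(all(diff(sums) <= 0L))
})

test_that("one extension step: unanimity extends, silence stops", {
  set.seed(13)
  full <- rnd_dna(120)
  contig <- substr(full, 1, 60)
  offs <- seq(10, 50, by = 8)
  reads <- data.frame(id = seq_along(offs),
                      seq1 = substring(full, offs, offs + 39),
                      seq2 = replicate(length(offs), rnd_dna(40)),
                      stringsAsFactors = FALSE)
  idx <- build_kmer_index(reads, cfg15)
  st <- extend_step(contig, idx, cfg15)
  expect_equal(st$action, "extend")
  expect_equal(st$base, substr(full, 61, 61))
  # a contig no read overlaps is a gap
  st2 <- extend_step(rnd_dna(60), idx, cfg15)
  expect_equal(st2$action, "stop")
})

test_that("paired-end pools decide before single-end reads are consulted", {
  set.seed(14)
  contig <- rnd_dna(600)
  cont <- paste0("C", rnd_dna(99))   # true continuation starts with C
  ins <- list(mean = 370, sd = 30, n = 100L)
  pairs <- NULL
  for (ov in seq(30, 57, by = 3)) {          # ten bridging pairs
    off <- 600L - ov
    rev_seq <- revcomp_dna(paste0(substr(contig, off + 1, 600),
                                  substr(cont, 1, 100 - ov)))
    mate_off <- off + 100L - 370L
    fwd_seq <- substr(contig, mate_off + 1, mate_off + 100)
    pairs <- rbind(pairs, data.frame(seq1 = fwd_seq, seq2 = rev_seq))
  }
  # three single-end reads with long overlaps voting T instead
  for (i in 1:3)
    pairs <- rbind(pairs, data.frame(
      seq1 = paste0(substr(contig, 521, 600), "T", rnd_dna(19)),
      seq2 = rnd_dna(100)))
  pairs <- data.frame(id = seq_len(nrow(pairs)), pairs,
                      stringsAsFactors = FALSE)
  idx <- build_kmer_index(pairs, cfg15)
  st <- extend_step(contig, idx, cfg15, insert = ins)
  expect_equal(st$mode, "paired")      # single-end tallies never consulted
  expect_equal(st$action, "extend")
  expect_equal(st$base, "C")
})

test_that("read acceptance classifies clean, bubble and dead-end reads", {
  cfg <- assembly_config()
  path <- rnd_dna(150)
  r_clean <- substr(path, 1, 100)
  expect_equal(read_accept(r_clean, path, cfg)$class, "clean")
  # two isolated substitutions: 98% similarity, tolerated bubble
  r_bub <- r_clean
  substr(r_bub, 20, 20) <- if (substr(r_bub, 20, 20) == "A") "C" else "A"
  substr(r_bub, 70, 70) <- if (substr(r_bub, 70, 70) == "A") "C" else "A"
  acc <- read_accept(r_bub, path, cfg)
  expect_true(acc$accept)
  expect_equal(acc$class, "bubble")
  # ten mismatched tail bases: 90% similarity, rejected as a dead end
  r_bad <- paste0(substr(r_clean, 1, 90),
                  chartr("ACGT", "GTAC", substr(r_clean, 91, 100)))
  acc2 <- read_accept(r_bad, path, cfg)
  expect_false(acc2$accept)
  expect_equal(acc2$class, "dead_end_reject")
})

test_that("insert model uses sample statistics of inward full pairs", {
  p2 <- data.frame(read_id = c(1L, 1L, 2L, 2L), mate = c(1L, 2L, 1L, 2L),
                   off = c(0L, 200L, 10L, 210L),
                   strand = c("+", "-", "+", "-"),
                   stringsAsFactors = FALSE)
  pools <- fake_pools(fake_pool1(character(0)), pool2 = p2)
  m <- update_insert_model("x", pools)
  expect_equal(m$mean, 300)
  expect_equal(m$sd, 0)
  p2b <- p2; p2b$off <- c(10L, 200L, 0L, 210L)   # spans 290 and 310
  m2 <- update_insert_model("x", fake_pools(fake_pool1(character(0)),
                                            pool2 = p2b))
  expect_equal(m2$mean, 300)
  expect_equal(m2$sd, sqrt(200), tolerance = 1e-10)
  expect_error(update_insert_model("x",
    fake_pools(fake_pool1(character(0)))), "at least 2")
})

test_that("error-free repeat-free reads reassemble the genome exactly", {
  for (k in c(21L, 31L)) {
    fx <- small_sim(G = 8000, coverage = 40, seed = 15)
    cfg <- assembly_config(k = k, O_max = 70, navigation = "heuristic",
                           seed = 15)
    asm <- assemble_contigs(fx$sim$pairs, cfg)
    expect_equal(length(asm$contigs), 1L)
    best <- asm$contigs[[1]]
    expect_true(best == fx$genome$seq || revcomp_dna(best) == fx$genome$seq)
    # every appended base had read support: no branch shows a zero tally
    if (nrow(asm$trace))
      expect_true(all(asm$trace$maxOcc[asm$trace$action == "extend"] >= 1L))
  }
})

test_that("reads from disjoint genomes assemble without chimeras", {
  fa <- small_sim(G = 6000, coverage = 40, seed = 16)
  fb <- small_sim(G = 6000, coverage = 40, seed = 17)
  pairs <- rbind(fa$sim$pairs, fb$sim$pairs)
  pairs$id <- seq_len(nrow(pairs))
  cfg <- assembly_config(navigation = "heuristic", seed = 16)
  asm <- assemble_contigs(pairs, cfg)
  expect_gte(length(asm$contigs), 2L)
  big <- asm$contigs[nchar(asm$contigs) >= 1000]
  simA <- call_misassemblies(big, fa$genome$seq)$records$similarity
  simB <- call_misassemblies(big, fb$genome$seq)$records$similarity
  expect_true(all(pmax(simA, simB) >= 0.95))
})

test_that("empty read sets are rejected up front", {
  empty <- data.frame(id = integer(0), seq1 = character(0),
                      seq2 = character(0))
  expect_error(build_kmer_index(empty, cfg15), "no reads")
})
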