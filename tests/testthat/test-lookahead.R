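cfgla <- test_cfg()

test_that("consensus verdict counts low-majority columns", {
  tail <- rnd_dna(40)
  # identical paths: no bad columns, continue
  p <- fake_path("ACGTACGTACGTACGTACGT",
                 reads = path_reads(tail, "ACGTACGTACGTACGTACGT"))
  v <- consensus_verdict(list(p, p), cfgla)
  expect_equal(v$verdict, "CONTINUE")
  expect_equal(v$bad_columns, 0L)
  expect_equal(v$base, "A")
})

test_that("verdict threshold arithmetic: 2 bad columns pass, 3 do not", {
  # hand-built column votes: 10 reads, a minority of 4 at chosen columns
  mk <- function(bad_cols) {
    seqs <- rep("AAAAAAAAAA", 10)
    for (cc in bad_cols)
      for (r in 7:10)  # 4 of 10 votes differ: ratio 0.6 < 0.9
        substr(seqs[r], cc, cc) <- "G"
    rd <- data.frame(read_id = 1:10, off = 0L, seq = seqs,
                     stringsAsFactors = FALSE)
    # two paths defined over the same 10 columns
    list(fake_path("AAAAAAAAAA", reads = rd[1:6, ]),
         fake_path("AAAAAAAAAG", reads = rd[7:10, ]))
  }
  # the branch column itself stays clean so the count rule decides
  v2 <- consensus_verdict(mk(c(4, 7)), cfgla)
  expect_equal(v2$verdict, "CONTINUE")   # 2 < max_bad_positions
  v3 <- consensus_verdict(mk(c(4, 7, 9)), cfgla)
  expect_equal(v3$verdict, "CHECK_REPEATS")
  expect_equal(v3$bad_columns, 3L)
})

test_that("tandem resolution merges on significant path overlap only", {
  set.seed(30)
  core <- rnd_dna(15)
  lead <- paste0("A", rnd_dna(14), core)          # suffix = core
  trail <- paste0(core, rnd_dna(15))              # prefix = core
  r <- resolve_tandem(list(fake_path(lead), fake_path(trail)),
                      insert = NULL, cfg = cfgla)
  expect_equal(r$action, "MERGE")
  expect_equal(r$i, 1L)       # extension continues along the leading path
  expect_gte(r$overlap, 15L)
  # no overlap of more than 10 bp: distant copies, stop
  r2 <- resolve_tandem(list(fake_path(rnd_dna(30)),
                            fake_path(rnd_dna(30))), NULL, cfgla)
  expect_equal(r2$action, "STOP")
  # boundary: an overlap of exactly 10 bp is not significant (strict >)
  core10 <- rnd_dna(10)
  r3 <- resolve_tandem(list(fake_path(paste0(rnd_dna(20), core10)),
                            fake_path(paste0(core10, rnd_dna(20)))),
                       NULL, cfgla)
  expect_equal(r3$action, "STOP")
})

test_that("convergent paths are never treated as two repeat copies", {
  s <- rnd_dna(50)
  a <- paste0("A", substr(s, 2, 50))
  b <- paste0("G", substr(s, 2, 50))   # differ at the first base only
  r <- resolve_tandem(list(fake_path(a), fake_path(b)), NULL, cfgla)
  expect_equal(r$action, "STOP")       # shift ~ 0 is not a tandem merge
  expect_true(pegasm:::paths_converge(list(fake_path(a), fake_path(b)),
                                      cfgla))
})

test_that("spurious paths need both high mismatch and bad insert spans", {
  ins <- list(mean = 370, sd = 56, n = 100L)
  good <- fake_path(rnd_dna(30), mm = 1L, pair_d = rep(370, 5))
  far <- fake_path(rnd_dna(30), mm = 3L, pair_d = rep(370 + 3 * 56, 5))
  mm_only <- fake_path(rnd_dna(30), mm = 3L, pair_d = rep(390, 5))
  dist_only <- fake_path(rnd_dna(30), mm = 1L, pair_d = rep(370 + 5 * 56, 5))
  pr <- prune_spurious_paths(list(good, far, mm_only, dist_only), ins, cfgla)
  expect_equal(length(pr$paths), 3L)   # only `far` removed (conjunction)
  # reads of removed paths are released, none lost
  far2 <- fake_path(rnd_dna(30), mm = 5L, pair_d = rep(800, 4),
                    reads = data.frame(read_id = 7:9, off = 0L,
                                       seq = "ACGT"))
  pr2 <- prune_spurious_paths(list(good, far2), ins, cfgla)
  expect_equal(pr2$released, 7:9)
})

test_that("path extraction separates error bubbles from repeat copies", {
  set.seed(31)
  # (a) branch caused by erroneous reads: paths share one continuation
  fx <- small_sim(G = 4000, coverage = 40, seed = 31)
  idx <- build_kmer_index(fx$sim$pairs, cfgla)
  G <- fx$genome$seq
  contig <- substr(G, 501, 1500)
  # inject three reads with the same substitution right after the branch
  bad <- substr(G, 1451, 1550)
  truebase <- substr(bad, 51, 51)
  wrongbase <- setdiff(BASES, truebase)[1]
  substr(bad, 51, 51) <- wrongbase
  inject <- data.frame(id = max(fx$sim$pairs$id) + 1:3,
                       seq1 = bad, seq2 = replicate(3, rnd_dna(100)),
                       stringsAsFactors = FALSE)
  cfg1 <- test_cfg(min_insert_n = .Machine$integer.max)  # single-end view
  idx2 <- build_kmer_index(rbind(fx$sim$pairs, inject), cfg1)
  paths <- extract_paths(contig, idx2, cfg1)
  expect_gte(length(paths), 2L)
  firsts <- vapply(paths, function(p) p$first_base, "")
  expect_true(truebase %in% firsts && wrongbase %in% firsts)
  # the wrong-base path converges back onto the true continuation
  pt <- paths[[which(firsts == truebase)[1]]]
  pw <- paths[[which(firsts == wrongbase)[1]]]
  if (nchar(pw$seq) > 20) {
    expect_equal(substr(pt$seq, 2, 20), substr(pw$seq, 2, 20))
  }
  # (b) a single candidate base gives a single (degenerate) path
  p1 <- extract_paths(substr(G, 501, 1500), idx, cfg1)
  expect_gte(length(p1), 1L)
})

test_that("tandem branches yield overlapping paths the resolver merges", {
  set.seed(32)
  nest <- repeat_spec(105, 3, 12)
  g <- generate_genome(12000, list(nest), seed = 32)
  sim <- simulate_pairs(g, coverage = 50, err_rate = 0, seed = 32)
  cfg <- assembly_config(navigation = "heuristic", seed = 32)
  asm <- assemble_contigs(sim, cfg)
  # the array is traversed into one contig that reaches both flanks
  best <- asm$contigs[[which.max(nchar(asm$contigs))]]
  if (!grepl(substr(g$seq, 1, 100), best, fixed = TRUE))
    best <- revcomp_dna(best)
  ann <- g$annotation
  lflank <- substr(g$seq, min(ann$start) - 200, min(ann$start) - 1)
  rflank <- substr(g$seq, max(ann$end) + 1, max(ann$end) + 200)
  expect_true(grepl(lflank, best, fixed = TRUE))
  expect_true(grepl(rflank, best, fixed = TRUE))
})

test_that("dead-end candidate paths are eliminated before the verdict", {
  ins <- list(mean = 370, sd = 56, n = 100L, read_len = 100L)
  resolver <- pegasm:::make_lookahead_resolver(test_cfg())
  live <- fake_path(rnd_dna(200),
                    reads = path_reads(rnd_dna(30), rnd_dna(200)))
  dead <- fake_path(rnd_dna(25), died_early = TRUE)
  out <- resolver(list(live, dead), ins)
  expect_equal(out$action, "extend")
  expect_equal(out$base, live$first_base)
  expect_equal(out$stage, "error")
})
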