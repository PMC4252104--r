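cfgsc <- test_cfg()

test_that("gap estimation averages the margin-distance formula", {
  ins <- list(mean = 370, sd = 56, n = 100L)
  expect_equal(estimate_gap(data.frame(d_a = 150, d_b = 150), ins), 70)
  expect_equal(estimate_gap(data.frame(d_a = c(100, 120),
                                       d_b = c(100, 80)),
                            list(mean = 300, sd = 10, n = 10L)), 100)
  expect_error(estimate_gap(data.frame(d_a = numeric(0),
                                       d_b = numeric(0)), ins),
               "no bridging")
})

test_that("gap estimator recovers a planted gap from simulated pairs", {
  # sample (d_a, d_b) under the estimator's model: insert F ~ N(370, 56),
  # true gap g, d_a + d_b = F - g with a uniform split
  set.seed(40)
  g_true <- 50; n <- 200
  f <- rnorm(n, 370, 56)
  d_a <- runif(n, 10, f - g_true - 10 - 100)
  d_b <- f - g_true - d_a
  est <- estimate_gap(data.frame(d_a = d_a, d_b = d_b),
                      list(mean = 370, sd = 56, n = 1000L))
  expect_lt(abs(est - g_true), 3 * 56 / sqrt(n))
})

test_that("bridging pairs vote the correct placement, uniquely mapped only", {
  set.seed(41)
  fx <- small_sim(G = 12000, coverage = 50, seed = 41)
  G <- fx$genome$seq
  contigs <- c(a = substr(G, 1, 5800), b = substr(G, 6001, 12000))
  idx <- build_kmer_index(fx$sim$pairs, cfgsc)
  gr <- build_scaffold_graph(contigs, idx, cfgsc)
  e <- gr$edges[["1|2"]]
  expect_false(is.null(e))
  expect_equal(names(which.max(e$w)), "++")
  expect_equal(sum(e$w[c("+-", "-+", "--")]), 0L)
  # contigs from unrelated sequence share no edge
  g2 <- generate_genome(6000, seed = 99)
  gr2 <- build_scaffold_graph(c(a = contigs[["a"]], z = g2$seq), idx,
                              cfgsc)
  expect_null(gr2$edges[["1|2"]])
  # a read matching two contigs maps ambiguously and contributes nothing
  dup <- c(a = substr(G, 1, 5800), b = substr(G, 6001, 12000),
           a2 = substr(G, 1, 5800))
  gr3 <- build_scaffold_graph(dup, idx, cfgsc)
  e3 <- gr3$edges[["1|2"]]
  expect_true(is.null(e3) || sum(e3$w) < sum(e$w) / 2)
})

test_that("greedy linking recovers order and orientation of genome cuts", {
  set.seed(42)
  fx <- small_sim(G = 18000, coverage = 50, seed = 42)
  G <- fx$genome$seq
  cuts <- list(c(1, 6000), c(6051, 12000), c(12101, 18000))
  contigs <- vapply(cuts, function(cc) substr(G, cc[1], cc[2]), "")
  names(contigs) <- c("c1", "c2", "c3")
  contigs["c2"] <- revcomp_dna(contigs["c2"])   # flip the middle contig
  idx <- build_kmer_index(fx$sim$pairs, cfgsc)
  ins <- list(mean = 370, sd = 56, n = 1000L)
  sc <- scaffold_contigs(contigs, idx, cfgsc, insert = ins,
                         fill_gaps = FALSE)
  chains <- sc$chains[vapply(sc$chains, nrow, 1L) > 1L]
  expect_equal(length(chains), 1L)
  ch <- chains[[1]]
  # order c1-c2-c3 (or its mirror), middle contig counter-oriented
  nm <- ch$name
  if (nm[1] == "c3") {
    nm <- rev(nm)
    ch <- ch[rev(seq_len(nrow(ch))), ]
    ch$orientation <- ifelse(ch$orientation == "+", "-", "+")
  }
  expect_equal(nm, c("c1", "c2", "c3"))
  expect_equal(ch$orientation, c("+", "-", "+"))
})

test_that("undifferentiated candidates terminate the extension", {
  # two identical right-neighbour candidates with equal weight: stop
  g1 <- generate_genome(6000, seed = 43)$seq
  fxa <- simulate_pairs(g1, coverage = 50, seed = 43)
  contigs <- c(a = substr(g1, 1, 2800),
               b1 = substr(g1, 3001, 6000),
               b2 = substr(g1, 3001, 6000))  # duplicated neighbour
  idx <- build_kmer_index(fxa$pairs, cfgsc)
  ins <- list(mean = 370, sd = 56, n = 1000L)
  sc <- scaffold_contigs(contigs, idx, cfgsc, insert = ins,
                         fill_gaps = FALSE)
  expect_true(all(vapply(sc$chains, nrow, 1L) == 1L))
})

test_that("junction resolution merges agreeing overlaps and gaps the rest", {
  set.seed(44)
  ins <- list(mean = 370, sd = 56, n = 500L)
  cfg <- assembly_config()
  G <- rnd_dna(4000)
  left <- substr(G, 1, 2020)
  right <- substr(G, 2001, 4000)     # true overlap 20
  r <- resolve_junction(left, right, gap_estimate = -20, ins, cfg)
  expect_equal(r$status, "merged")
  expect_equal(r$overlap, 20L)
  # a large positive estimate stays gapped without an alignment attempt
  r2 <- resolve_junction(left, rnd_dna(2000), gap_estimate = 500, ins, cfg)
  expect_equal(r2$status, "gapped")
  expect_equal(r2$gap, 500L)
  # a 3-mer end match is below the merge floor (strict > 3)
  l3 <- paste0(rnd_dna(500), "ACG")
  r3 <- paste0("ACG", rnd_dna(500))
  res3 <- resolve_junction(l3, r3, gap_estimate = -3, ins, cfg)
  expect_equal(res3$status, "gapped")
})

test_that("scaffold sequences splice junctions as resolved", {
  set.seed(45)
  fx <- small_sim(G = 12000, coverage = 50, seed = 45)
  G <- fx$genome$seq
  idx <- build_kmer_index(fx$sim$pairs, cfgsc)
  ins <- list(mean = 370, sd = 56, n = 1000L)
  # overlapping cuts merge seamlessly
  co <- c(a = substr(G, 1, 6030), b = substr(G, 6001, 12000))
  sc <- scaffold_contigs(co, idx, cfgsc, insert = ins, fill_gaps = FALSE)
  expect_equal(unname(nchar(sc$sequences[1])), 12000L)
  expect_true(sc$sequences[[1]] == G || revcomp_dna(sc$sequences[[1]]) == G)
  # gapped cuts carry an N run; gap filling then closes it exactly
  cg <- c(a = substr(G, 1, 5950), b = substr(G, 6001, 12000))
  sg <- scaffold_contigs(cg, idx, cfgsc, insert = ins, fill_gaps = FALSE)
  expect_true(grepl("N", sg$sequences[[1]], fixed = TRUE))
  sf <- scaffold_contigs(cg, idx, cfgsc, insert = ins, fill_gaps = TRUE)
  expect_false(grepl("N", sf$sequences[[1]], fixed = TRUE))
  expect_true(sf$sequences[[1]] == G || revcomp_dna(sf$sequences[[1]]) == G)
  # FASTA emission round-trips
  f <- tempfile(fileext = ".fa")
  emit_scaffolds(sf, f)
  expect_equal(unname(read_fasta(f)[1]), unname(sf$sequences[1]))
})

test_that("singleton scaffolds appear when no contig seeds a chain", {
  g <- generate_genome(4000, seed = 46)
  sim <- simulate_pairs(g, coverage = 30, seed = 46)
  idx <- build_kmer_index(sim$pairs, cfgsc)
  short <- c(x = substr(g$seq, 100, 400), y = substr(g$seq, 3000, 3300))
  cfg_big <- test_cfg(linking_region = 2000L)  # longer than any contig
  sc <- scaffold_contigs(short, idx, cfg_big,
                         insert = list(mean = 370, sd = 56, n = 100L),
                         fill_gaps = FALSE)
  expect_equal(length(sc$sequences), 2L)
  expect_true(all(vapply(sc$chains, nrow, 1L) == 1L))
})
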