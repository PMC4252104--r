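test_that("N50 matches its definition and the brute force", {
  expect_equal(n50(1000), 1000)
  expect_equal(n50(c(1, 1, 1, 1, 4)), 4)
  expect_equal(n50(c(2, 2, 2)), 2)
  expect_error(n50(numeric(0)))
  expect_error(n50(c(3, -1)))
  # brute force: largest L with sum(lengths >= L) >= total/2
  brute_n50 <- function(v) {
    max(Filter(function(L) sum(v[v >= L]) >= sum(v) / 2, sort(unique(v))))
  }
  set.seed(50)
  for (i in 1:100) {
    v <- sample(1:500, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(v), brute_n50(v))
  }
})

test_that("reference comparison: identity, strandness and chimeras", {
  set.seed(51)
  ref <- rnd_dna(8000)
  # the reference itself: full coverage, no mis-assembly
  r <- call_misassemblies(c(whole = ref), ref)
  expect_equal(r$coverage, 1.0)
  expect_equal(nrow(r$misassembled), 0L)
  expect_equal(r$records$similarity, 1.0)
  # a reverse-complement segment is covered and clean
  seg <- revcomp_dna(substr(ref, 2001, 4000))
  r2 <- call_misassemblies(c(rcseg = seg), ref)
  expect_equal(nrow(r2$misassembled), 0L)
  expect_equal(r2$records$strand, "-")
  expect_equal(r2$coverage, 2000 / 8000, tolerance = 0.01)
  # a chimera fusing two distant loci is mis-assembled
  chi <- paste0(substr(ref, 1, 700), substr(ref, 5000, 5700))
  r3 <- call_misassemblies(c(chimera = chi), ref)
  expect_equal(nrow(r3$misassembled), 1L)
  expect_lt(r3$records$similarity, 0.95)
  # records under the length floor are excluded
  r4 <- call_misassemblies(c(tiny = substr(ref, 1, 80)), ref)
  expect_null(r4$records)
})

test_that("a few scattered substitutions stay under the 95% rule", {
  set.seed(52)
  ref <- rnd_dna(5000)
  rec <- substr(ref, 1001, 3000)
  for (p in c(100, 900, 1700))
    substr(rec, p, p) <- setdiff(BASES, substr(rec, p, p))[1]
  r <- call_misassemblies(c(x = rec), ref)
  expect_gte(r$records$similarity, 1 - 3 / 2000 - 1e-9)
  expect_equal(nrow(r$misassembled), 0L)
})

test_that("repeat records credit coverage at all their loci", {
  set.seed(53)
  ref0 <- rnd_dna(6000)
  seg <- substr(ref0, 1001, 1800)
  ref <- ref0
  substr(ref, 4001, 4800) <- seg    # two copies of an 800 bp segment
  r <- call_misassemblies(c(rep1 = seg), ref)
  expect_gte(nrow(r$records), 1L)
  expect_equal(r$coverage, 1600 / 6000, tolerance = 0.05)
})

test_that("branch ledger cross-tabulates and sums to the trace size", {
  set.seed(54)
  truth <- rnd_dna(3000)
  ctx <- substr(truth, 1001, 1500)
  nxt <- substr(truth, 1501, 1501)
  trace <- data.frame(
    context = rep(ctx, 10),
    action = c(rep("extend", 8), "stop", "extend"),
    base = c(rep(nxt, 8), "", setdiff(BASES, nxt)[1]),
    stage = c(rep("svm", 7), "lookahead_error", "svm", "lookahead_repeat"),
    mode = "single", stringsAsFactors = FALSE)
  led <- tally_branches(trace, truth)
  expect_equal(led$n, 10L)
  expect_equal(sum(led$overall), 10L)
  expect_equal(unname(led$overall["correct_extension"]), 8L)
  expect_equal(unname(led$overall["incorrect_stop"]), 1L)
  expect_equal(unname(led$overall["incorrect_extension"]), 1L)
  # brute-force recount of the same trace
  lab <- label_branches(trace, truth)
  expect_equal(unname(led$overall["correct_extension"]),
               sum(lab$outcome_class == "correct_extension"))
  # look-ahead sub-ledger splits by stage
  expect_equal(led$lookahead$error[["correct"]], 1L)
  expect_equal(led$lookahead$`repeat`[["incorrect"]], 1L)
})

test_that("evaluate_assembly bundles the metrics", {
  fx <- small_sim(G = 6000, coverage = 40, seed = 55)
  cfg <- assembly_config(navigation = "heuristic", seed = 55)
  asm <- assemble_contigs(fx$sim$pairs, cfg)
  ev <- evaluate_assembly(asm, fx$genome, trace = asm$trace)
  expect_equal(ev$n_records, length(asm$contigs))
  expect_gte(ev$coverage, 0.99)
  expect_equal(nrow(ev$misassembled), 0L)
  expect_equal(ev$n50, max(nchar(asm$contigs)))
})
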