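test_that("the polynomial kernel matches its closed form", {
  # <x,y> = 0, 1, 2 give 0, 4, 18
  expect_equal(svm_kernel(c(1, 0), c(0, 1)), 0)
  expect_equal(svm_kernel(c(1, 0, 0, 0), c(1, 0, 0, 0)), 4)
  expect_equal(svm_kernel(c(1, 1), c(1, 1)), 18)
  set.seed(20)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    d <- sum(x * y)
    expect_equal(svm_kernel(x, y), d * (1 + d)^2)
    # K(x,x) = ||x||^2 (1 + ||x||^2)^2, positive
    n2 <- sum(x * x)
    expect_equal(svm_kernel(x, x), n2 * (1 + n2)^2)
    expect_gte(svm_kernel(x, x), 0)
  }
})

test_that("branch features follow their definitions", {
  # tallies {C:10, T:2}, uniform coverage, last full read flush with end
  p1 <- fake_pool1(c(rep("C", 10), rep("T", 2)), paired = TRUE)
  p2 <- data.frame(read_id = 1L, mate = 1L, off = 100L, strand = "+",
                   stringsAsFactors = FALSE)
  pools <- fake_pools(p1, pool2 = p2, support = rep(5L, 200L),
                      read_len = 100L)
  f <- compute_features(strrep("A", 200), pools, "paired")
  expect_equal(unname(f["maxOcc"]), 10)
  expect_equal(unname(f["secOcc"]), 2)
  expect_equal(unname(f["gapLen"]), 0)   # read ends at position 200
  # uniform support + full-width partials keep the ratio near 1
  expect_gt(f[["covRatio"]], 0.9)
  # a single candidate base is not a branch
  single <- fake_pools(fake_pool1(rep("C", 5), paired = TRUE), pool2 = p2)
  expect_error(compute_features("x", single, "paired"), "not a branch")
})

test_that("elevated end density shows up as covRatio above one", {
  p1 <- fake_pool1(c(rep("A", 5), rep("G", 5)), overlap = 200L)
  p2 <- data.frame(read_id = 1:2, mate = c(1L, 1L), off = c(100L, 300L),
                   strand = c("+", "+"), stringsAsFactors = FALSE)
  pools <- fake_pools(p1, pool2 = p2, support = rep(2L, 400L),
                      read_len = 100L)
  f <- compute_features(strrep("A", 400), pools, "single", O = 15)
  expect_equal(unname(f["maxOcc"]), 5)
  expect_equal(unname(f["secOcc"]), 5)
  expect_gt(f[["covRatio"]], 1.5)   # partial pile-up at the end
})

test_that("training on separable branches reproduces the labels", {
  set.seed(21)
  n <- 100
  cont <- data.frame(maxOcc = rpois(n, 30) + 10, secOcc = rpois(n, 2),
                     covRatio = rnorm(n, 1, 0.05),
                     gapLen = rpois(n, 2),
                     label = "CONTINUE", stringsAsFactors = FALSE)
  stop <- data.frame(maxOcc = rpois(n, 8) + 4,
                     secOcc = rpois(n, 6) + 4,
                     covRatio = rnorm(n, 2, 0.2),
                     gapLen = rpois(n, 40) + 10,
                     label = "STOP", stringsAsFactors = FALSE)
  tr <- rbind(cont, stop)
  m <- train_navigator(tr, mode = "single", C = 1)
  expect_gte(m$training_accuracy, 0.95)
  # duplicated conflicting points: soft margin tolerates them
  clash <- rbind(tr, transform(tr[1:10, ], label = "STOP"))
  expect_no_error(train_navigator(clash, mode = "single"))
  expect_error(train_navigator(cont, mode = "single"), "both")
})

test_that("the decision function equals the brute-force dual expansion", {
  set.seed(22)
  n <- 60
  tr <- data.frame(maxOcc = c(rpois(n, 30) + 10, rpois(n, 6) + 3),
                   secOcc = c(rpois(n, 2), rpois(n, 6) + 3),
                   covRatio = c(rnorm(n, 1, 0.1), rnorm(n, 2, 0.2)),
                   gapLen = c(rpois(n, 2), rpois(n, 30) + 5),
                   label = rep(c("CONTINUE", "STOP"), each = n),
                   stringsAsFactors = FALSE)
  m <- train_navigator(tr, mode = "paired")
  x <- as.matrix(tr[sample(2 * n, 20), 1:4])
  d_pkg <- pegasm:::navigator_decision(m, x)
  # independent oracle: explicit sum over support vectors
  z <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  d_oracle <- apply(z, 1, function(v)
    sum(vapply(seq_len(nrow(m$sv)), function(i)
      m$coef[i] * svm_kernel(m$sv[i, ], v), 1)) + m$rho)
  expect_equal(unname(d_pkg), unname(d_oracle), tolerance = 1e-10)
  # and the C++ engine computes the same decision values
  cfg <- test_cfg(navigation = "svm")
  for (r in 1:5) {
    cls <- classify_branch(m, x[r, ], cfg)
    d <- attr(cls, "decision")
    expect_equal(unname(d), unname(d_oracle[r]), tolerance = 1e-10)
  }
})

test_that("classification separates confident calls from the margin band", {
  cfg <- assembly_config()
  # heuristic fallback: clear majority with support at the end continues
  expect_equal(classify_branch(NULL, c(10, 2, 1.0, 0), cfg), "CONTINUE")
  expect_equal(classify_branch(NULL, c(5, 5, 2.0, 40), cfg),
               "LOW_CONFIDENCE")
  # trained model: an exact tie can never be a confident CONTINUE
  m <- navigator_default()
  for (mode in c("single", "paired")) {
    out <- classify_branch(m[[mode]], c(5, 5, 2.0, 40), cfg)
    expect_true(out %in% c("STOP", "LOW_CONFIDENCE"))
    expect_equal(as.character(classify_branch(m[[mode]], c(10, 2, 1, 0),
                                              cfg)), "CONTINUE")
  }
  # boundary rule: |decision| exactly at the margin is low confidence
  m1 <- m$single
  feat <- c(10, 2, 1, 0)
  d <- pegasm:::navigator_decision(m1, matrix(feat, 1))
  m1$margin <- abs(d)
  expect_equal(as.character(classify_branch(m1, feat, cfg)),
               "LOW_CONFIDENCE")
})

test_that("branch labelling agrees with the truth sequence", {
  set.seed(23)
  truth <- rnd_dna(2000)
  ctx1 <- substr(truth, 501, 1000)
  nxt1 <- substr(truth, 1001, 1001)
  wrong <- setdiff(BASES, nxt1)[1]
  # a divergent context: two copies with different continuations
  seg <- substr(truth, 100, 299)
  truth2 <- paste0(truth, rnd_dna(50), seg, "A", rnd_dna(100))
  nxt_orig <- substr(truth2, 300, 300)
  div_ctx <- seg
  trace <- data.frame(
    context = c(ctx1, ctx1, ctx1, div_ctx, div_ctx, "GATTACAGATTACA"),
    action = c("extend", "extend", "stop", "stop", "extend", "extend"),
    base = c(nxt1, wrong, "", "", "A", "A"),
    stage = "heuristic", mode = "single",
    stringsAsFactors = FALSE)
  lab <- suppressWarnings(label_branches(trace, truth2))
  expect_equal(lab$outcome_class[1:3],
               c("correct_extension", "incorrect_extension",
                 "incorrect_stop"))
  if (nxt_orig != "A") {  # the two copies genuinely diverge
    expect_equal(lab$outcome_class[4], "correct_stop")
    expect_equal(lab$outcome_class[5], "incorrect_extension")
  }
  expect_true(is.na(lab$outcome_class[6]))  # context absent from truth
  expect_equal(lab$label[1], "CONTINUE")
  expect_equal(lab$label[3], "CONTINUE")    # wrong stop should continue
})

test_that("navigator models survive the plain-text round trip", {
  set.seed(24)
  n <- 40
  tr <- data.frame(maxOcc = c(rpois(n, 25) + 8, rpois(n, 5) + 3),
                   secOcc = c(rpois(n, 2), rpois(n, 5) + 3),
                   covRatio = c(rnorm(n, 1, 0.1), rnorm(n, 2, 0.3)),
                   gapLen = c(rpois(n, 3), rpois(n, 25) + 5),
                   label = rep(c("CONTINUE", "STOP"), each = n),
                   stringsAsFactors = FALSE)
  ms <- list(single = train_navigator(tr, "single"),
             paired = train_navigator(tr, "paired", margin = 0.8))
  f <- tempfile()
  write_navigator_model(ms, f)
  back <- read_navigator_model(f)
  for (mode in c("single", "paired")) {
    expect_equal(back[[mode]]$sv, ms[[mode]]$sv, ignore_attr = TRUE)
    expect_equal(back[[mode]]$coef, ms[[mode]]$coef)
    expect_equal(back[[mode]]$rho, ms[[mode]]$rho)
    expect_equal(back[[mode]]$margin, ms[[mode]]$margin)
    x <- matrix(c(12, 3, 1, 2), 1)
    expect_equal(pegasm:::navigator_decision(back[[mode]], x),
                 pegasm:::navigator_decision(ms[[mode]], x))
  }
})
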