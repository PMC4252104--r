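#!/usr/bin/env Rscript
# Regenerates inst/extdata/navigator_default.txt.
#
# Training protocol: assemble synthetic genomes with pure-majority branch
# decisions (no SVM, no look-ahead) and label every traced branch against
# the truth sequence.  The genomes carry short tandem arrays
# (look-ahead-scale ambiguity), mid-size duplications (resolvable by
# pairs, not by single reads) and long duplications (beyond the insert
# size, where stopping is correct).  The paired-feature model is trained
# on paired-mode branches of a normal run; the single-feature model on a
# run with the insert model disabled, so that every decision is made from
# single-end tallies.
library(pegasm)

plant_dup <- function(G, from, len, to) {
  substr(G, to, to + len - 1L) <- substr(G, from, from + len - 1L)
  G
}

make_genome <- function(seed) {
  g <- generate_genome(150000,
                       list(repeat_spec(60, 3, 30),
                            repeat_spec(80, 4, 40),
                            repeat_spec(50, 3, 25)),
                       seed = seed)
  G <- g$seq
  set.seed(seed + 1L)
  # eight long duplications (beyond the 370 +/- 56 insert span)
  don <- seq(10000, 80000, by = 10000)
  acc <- seq(90000, 146000, by = 8000)
  for (i in seq_along(don))
    G <- plant_dup(G, don[i], sample(700:1000, 1L), acc[i])
  # mid-size duplications: pairs resolve them, single reads cannot
  for (i in 1:4)
    G <- plant_dup(G, 15000 + 7000 * i, sample(150:300, 1L),
                   86000 + 900 * i)
  G
}

run_trace <- function(G, seed, single_only = FALSE) {
  cfg <- assembly_config(navigation = "majority", use_lookahead = FALSE,
                         seed = seed)
  if (single_only) cfg$min_insert_n <- .Machine$integer.max
  sim <- simulate_pairs(G, coverage = 50, read_len = 100,
                        insert_mean = 370, insert_sd = 56,
                        err_rate = 0.01, seed = seed)
  asm <- assemble_contigs(sim, cfg)
  label_branches(asm$trace, G)
}

lab_paired <- NULL
lab_single <- NULL
for (seed in c(101L, 202L)) {
  G <- make_genome(seed)
  lp <- run_trace(G, seed)
  ls <- run_trace(G, seed + 50L, single_only = TRUE)
  lab_paired <- rbind(lab_paired, lp[lp$mode == "paired", ])
  lab_single <- rbind(lab_single, rbind(lp[lp$mode == "single", ],
                                        ls[ls$mode == "single", ]))
}
cat("paired branches:\n"); print(table(lab_paired$label, useNA = "ifany"))
cat("single branches:\n"); print(table(lab_single$label, useNA = "ifany"))

models <- list()
for (mode in c("paired", "single")) {
  sub <- if (mode == "paired") lab_paired else lab_single
  sub <- sub[!is.na(sub$label), , drop = FALSE]
  if (length(unique(sub$label)) < 2L) {
    cat("mode", mode, ": single class, model not trained\n")
    next
  }
  m <- train_navigator(sub, mode = mode, C = 1, margin = 0.5,
                       max_points = 600L)
  print(m)
  models[[mode]] <- m
}
write_navigator_model(models, "inst/extdata/navigator_default.txt")
cat("wrote inst/extdata/navigator_default.txt (",
    file.size("inst/extdata/navigator_default.txt"), "bytes )\n")
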