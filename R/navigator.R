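#' Branch-navigation polynomial kernel
#'
#' K(x, y) = <x, y> * (1 + <x, y>)^2, i.e. a positive-coefficient series
#' in the dot product (d + 2 d^2 + d^3), hence a valid (positive
#' semi-definite) kernel.
#'
#' @param x,y numeric vectors of equal length.
#' @return Scalar kernel value.
#' @examples
#' svm_kernel(c(1, 0), c(0, 1))  # 0
#' svm_kernel(c(1, 0), c(1, 0))  # 1 * (1 + 1)^2 = 4
#' @export
svm_kernel <- function(x, y) {
  d <- sum(x * y)
  d * (1 + d)^2
}

#' Branch features at an extension point
#'
#' The four features the navigator sees: `maxOcc` and `secOcc` are the
#' read counts behind the best and second-best candidate base, `covRatio`
#' is the mean per-position aligned-read count within two read lengths of
#' the extending end divided by the mean over the whole contig (values
#' well above 1 flag a nearby repeat), and `gapLen` is the distance in bp
#' from the end of the last fully aligned read to the contig end (large
#' values flag thinning support).
#'
#' @param contig the contig the pools were computed on.
#' @param pools a `read_pools` from [align_candidates()].
#' @param mode `"paired"` or `"single"`.
#' @param O overlap threshold for single mode.
#' @return Named numeric vector `(maxOcc, secOcc, covRatio, gapLen)`.
#' @export
compute_features <- function(contig, pools, mode = c("paired", "single"),
                             O = 0L) {
  mode <- match.arg(mode)
  tal <- tally_candidates(pools, mode, O)
  if (sum(tal > 0L) < 2L)
    stop("not a branch: fewer than two candidate bases have support")
  ord <- sort(tal, decreasing = TRUE)
  len <- nchar(contig)
  supp <- pools$support
  rl <- attr(pools, "read_len")
  if (is.null(rl)) rl <- 100L
  w <- min(len, 2L * rl)
  # end-window density includes partially aligned (pool-1) reads so the
  # measure does not droop by a read length at every extending end
  se <- sum(supp[(len - w + 1L):len])
  p1 <- pools$pool1
  if (nrow(p1))
    se <- se + sum(pmin(p1$overlap, w))
  cov_end <- se / w
  cov_all <- mean(supp)
  covRatio <- if (cov_all > 0) cov_end / cov_all else 1.0
  p2 <- pools$pool2
  last_full <- if (nrow(p2)) max(p2$off + rl) else 0L
  c(maxOcc = unname(ord[1L]), secOcc = unname(ord[2L]),
    covRatio = covRatio, gapLen = max(0L, len - last_full))
}

#' Label traced branches against a known truth sequence
#'
#' Each branch context (the contig's terminal `trace_context` bases at
#' decision time, about one insert span) is located in the truth sequence
#' on both strands.  When the context has a unique continuation, an
#' extension is correct iff the appended base equals it, and a stop is
#' incorrect.  When the context occurs at two or more truth loci with
#' divergent continuations -- an ambiguity that outruns the evidence even
#' paired reads can carry -- stopping is correct and any extension is a
#' gamble, hence incorrect; a context flush with the sequence end also
#' makes a stop correct.  The four outcome classes map to training
#' labels: CONTINUE for correct extensions and incorrect stops, STOP
#' otherwise.
#'
#' @param trace branch trace from [assemble_contigs()] (typically run
#'   with `navigation = "majority"` for training).
#' @param truth truth DNA string (or `synthetic_genome`).
#' @return The trace with columns `outcome_class`
#'   (correct/incorrect extension/stop, `NA` when the context cannot be
#'   located) and `label` (`"CONTINUE"`/`"STOP"`).
#' @export
label_branches <- function(trace, truth) {
  if (inherits(truth, "synthetic_genome")) truth <- truth$seq
  truth <- toupper(unname(truth)[1L])
  if (nrow(trace) == 0L) {
    trace$outcome_class <- character(0)
    trace$label <- character(0)
    return(trace)
  }
  tn <- cpp_truth_next(truth, trace$context)
  n_occ <- vapply(tn, `[[`, 1L, "n_occ")
  nxt <- vapply(tn, `[[`, "", "next")
  oc <- rep(NA_character_, nrow(trace))
  for (i in seq_len(nrow(trace))) {
    if (n_occ[i] == 0L) next
    bases <- gsub("\\$", "", nxt[i])
    at_end <- grepl("$", nxt[i], fixed = TRUE)
    divergent <- nchar(bases) >= 2L || at_end
    if (trace$action[i] == "extend") {
      oc[i] <- if (!divergent && grepl(trace$base[i], bases, fixed = TRUE))
        "correct_extension" else "incorrect_extension"
    } else {
      oc[i] <- if (divergent) "correct_stop" else "incorrect_stop"
    }
  }
  if (anyNA(oc))
    warning(sum(is.na(oc)), " branch context(s) could not be located in ",
            "the truth sequence and were skipped")
  trace$outcome_class <- oc
  trace$label <- ifelse(oc %in% c("correct_extension", "incorrect_stop"),
                        "CONTINUE",
                        ifelse(is.na(oc), NA_character_, "STOP"))
  trace
}

#' Train a navigator SVM on labelled branches
#'
#' Fits a soft-margin SVM with the package's polynomial kernel on
#' z-standardized branch features.  The quadratic program is solved by
#' \pkg{kernlab}; the stored model keeps the support vectors, dual
#' coefficients, bias and scaler so that classification at assembly time
#' is the explicit dual expansion sum_i coef_i K(sv_i, z) + rho.
#'
#' @param branches labelled trace from [label_branches()], or any
#'   `data.frame` with columns `maxOcc`, `secOcc`, `covRatio`, `gapLen`
#'   and `label` (`"CONTINUE"`/`"STOP"`).
#' @param mode which branch mode the model is for (stored, not used in
#'   fitting): `"paired"` or `"single"`.
#' @param C soft-margin penalty.
#' @param margin decision-value half-width of the low-confidence band.
#' @param max_points cap on training points (class-stratified subsample)
#'   to keep the model small.
#' @return Object of class `navigator_model`.
#' @export
train_navigator <- function(branches, mode = c("single", "paired"),
                            C = 1.0, margin = 0.5, max_points = 2000L) {
  mode <- match.arg(mode)
  feats <- c("maxOcc", "secOcc", "covRatio", "gapLen")
  stopifnot(all(feats %in% names(branches)), "label" %in% names(branches))
  branches <- branches[!is.na(branches$label), , drop = FALSE]
  y <- branches$label
  if (length(unique(y)) < 2L)
    stop("training data must contain both CONTINUE and STOP branches")
  if (nrow(branches) > max_points) {
    set.seed(1L)
    keep <- unlist(lapply(split(seq_len(nrow(branches)), y), function(ix)
      if (length(ix) > max_points %/% 2L)
        sample(ix, max_points %/% 2L) else ix))
    branches <- branches[sort(keep), , drop = FALSE]
    y <- branches$label
  }
  x <- as.matrix(branches[, feats])
  storage.mode(x) <- "double"
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  kern <- function(a, b) { d <- sum(a * b); d * (1 + d)^2 }
  class(kern) <- "kernel"
  yy <- factor(y, levels = c("CONTINUE", "STOP"))
  fit <- kernlab::ksvm(z, yy, kernel = kern, C = C, scaled = FALSE)
  svi <- kernlab::alphaindex(fit)[[1L]]
  model <- structure(list(
    mode = mode,
    sv = z[svi, , drop = FALSE],
    coef = kernlab::coef(fit)[[1L]],
    rho = -kernlab::b(fit),
    margin = margin,
    center = center, scale = scale,
    n_train = nrow(z)), class = "navigator_model")
  # orient the decision function so positive means CONTINUE
  dv <- navigator_decision(model, x)
  agree <- mean((dv > 0) == (y == "CONTINUE"))
  if (agree < 0.5) {
    model$coef <- -model$coef
    model$rho <- -model$rho
    agree <- 1 - agree
  }
  model$training_accuracy <- agree
  model
}

# decision values for a raw (unscaled) feature matrix
navigator_decision <- function(model, x) {
  x <- matrix(as.numeric(x), ncol = 4L)
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  apply(z, 1L, function(v) {
    d <- as.numeric(model$sv %*% v)
    sum(model$coef * d * (1 + d)^2) + model$rho
  })
}

#' Classify a branch with a trained navigator (or the heuristic fallback)
#'
#' Decision values strictly outside the low-confidence band decide by
#' sign (positive continues); values inside the band -- boundary included
#' -- are low confidence and handed to the look-ahead.  Without a trained
#' model the fallback heuristic continues when secOcc/maxOcc < 0.7 and
#' the gap length is small, and reports low confidence otherwise.
#'
#' @param model a `navigator_model`, or `NULL` for the heuristic.
#' @param features numeric vector `(maxOcc, secOcc, covRatio, gapLen)`.
#' @param cfg an [assembly_config()] (heuristic thresholds).
#' @return `"CONTINUE"`, `"STOP"` or `"LOW_CONFIDENCE"`, with the
#'   decision value as attribute `decision` when a model is used.
#' @export
classify_branch <- function(model, features, cfg = assembly_config()) {
  features <- as.numeric(features)
  if (is.null(model)) {
    ok <- features[1L] > 0 && features[2L] / features[1L] < cfg$heur_ratio &&
      features[4L] <= cfg$heur_gap
    return(if (ok) "CONTINUE" else "LOW_CONFIDENCE")
  }
  stopifnot(inherits(model, "navigator_model"))
  d <- navigator_decision(model, matrix(features, nrow = 1L))
  out <- if (abs(d) <= model$margin) "LOW_CONFIDENCE"
         else if (d > 0) "CONTINUE" else "STOP"
  # a dead tie (maxOcc == secOcc) has no majority base: never CONTINUE
  if (out == "CONTINUE" && features[1L] <= features[2L])
    out <- "LOW_CONFIDENCE"
  attr(out, "decision") <- d
  out
}

#' @export
print.navigator_model <- function(x, ...) {
  cat("navigator_model (", x$mode, "): ", nrow(x$sv), " support vectors, ",
      "margin ", x$margin, ", training accuracy ",
      round(100 * x$training_accuracy, 2), "%\n", sep = "")
  invisible(x)
}

#' Write/read a navigator model as plain text
#'
#' @param model a `navigator_model` or a `list(single =, paired =)` pair
#'   of them.
#' @param path file path.
#' @return `read_navigator_model()` returns what was written (single
#'   model or two-mode list); `write_navigator_model()` returns `path`
#'   invisibly.
#' @export
write_navigator_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  models <- if (inherits(model, "navigator_model")) list(model) else
    Filter(Negate(is.null), model[c("single", "paired")])
  for (m in models) {
    writeLines(sprintf("mode\t%s", m$mode), con)
    writeLines(sprintf("rho\t%.17g", m$rho), con)
    writeLines(sprintf("margin\t%.17g", m$margin), con)
    writeLines(paste0("center\t", paste(sprintf("%.17g", m$center),
                                        collapse = "\t")), con)
    writeLines(paste0("scale\t", paste(sprintf("%.17g", m$scale),
                                       collapse = "\t")), con)
    writeLines(sprintf("nsv\t%d", nrow(m$sv)), con)
    for (i in seq_len(nrow(m$sv)))
      writeLines(paste(sprintf("%.17g", c(m$coef[i], m$sv[i, ])),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_navigator_model
#' @export
read_navigator_model <- function(path) {
  lines <- readLines(path)
  models <- list()
  i <- 1L
  while (i <= length(lines)) {
    fld <- strsplit(lines[i], "\t")[[1L]]
    stopifnot(fld[1L] == "mode")
    mode <- fld[2L]
    getv <- function(j) as.numeric(strsplit(lines[j], "\t")[[1L]][-1L])
    rho <- getv(i + 1L); margin <- getv(i + 2L)
    center <- getv(i + 3L); scale <- getv(i + 4L)
    nsv <- as.integer(getv(i + 5L))
    rows <- lapply(seq_len(nsv), function(r)
      as.numeric(strsplit(lines[i + 5L + r], "\t")[[1L]]))
    mat <- do.call(rbind, rows)
    m <- structure(list(mode = mode, sv = mat[, -1L, drop = FALSE],
                        coef = mat[, 1L], rho = rho, margin = margin,
                        center = setNames(center, c("maxOcc", "secOcc",
                                                    "covRatio", "gapLen")),
                        scale = setNames(scale, c("maxOcc", "secOcc",
                                                  "covRatio", "gapLen")),
                        n_train = NA_integer_,
                        training_accuracy = NA_real_),
                   class = "navigator_model")
    models[[mode]] <- m
    i <- i + 6L + nsv
  }
  if (length(models) == 1L) models[[1L]] else models
}

#' The bundled default navigator
#'
#' A two-mode model trained on this package's own simulation (see the
#' methods vignette for the training protocol); used when
#' `model = "default"` is passed to [assemble_contigs()].
#'
#' @return `list(single =, paired =)` of `navigator_model` objects.
#' @export
navigator_default <- function() {
  path <- system.file("extdata", "navigator_default.txt",
                      package = "pegasm")
  if (!nzchar(path)) stop("bundled navigator model not found")
  m <- read_navigator_model(path)
  if (inherits(m, "navigator_model")) list(single = m) else m
}
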