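#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length at least L together
#' cover at least half the total assembly size.
#'
#' @param lengths positive integer vector.
#' @return The N50 length.
#' @examples
#' n50(c(1, 1, 1, 1, 4))  # 4
#' n50(c(2, 2, 2))        # 2
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (!length(lengths) || any(lengths <= 0) || anyNA(lengths))
    stop("lengths must be a non-empty vector of positive values")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Align assembly records to a reference and call mis-assemblies
#'
#' Each record is anchored on the reference by shared k-mers (both
#' strands), its best anchor is verified by a banded global alignment of
#' the whole record, and records whose whole-length similarity falls
#' below `min_similarity` are called mis-assembled.  Reference coverage
#' counts a position as covered when any anchored interval of any record
#' spans it; a collapsed repeat record anchors at every copy, so all its
#' genomic loci count as covered.
#'
#' @param assembly named character vector of contigs/scaffolds (or an
#'   `assembly` / `scaffolds` object).
#' @param reference reference DNA string (or `synthetic_genome`).
#' @param min_similarity mis-assembly threshold (default 0.95).
#' @param min_len records shorter than this are excluded from the
#'   metrics.
#' @param k anchor k-mer size.
#' @param band band half-width of the global alignment (substitution-
#'   dominated assemblies need only a narrow band).
#' @return List with `coverage` (fraction of reference positions
#'   covered), `records` (per-record table: length, anchor, strand,
#'   similarity, misassembled), and `misassembled` (name/length subset).
#' @export
call_misassemblies <- function(assembly, reference, min_similarity = 0.95,
                               min_len = 100L, k = 31L, band = 50L) {
  recs <- assembly_records(assembly)
  if (inherits(reference, "synthetic_genome")) reference <- reference$seq
  reference <- toupper(unname(reference)[1L])
  recs <- recs[nchar(recs) >= min_len]
  if (!length(recs))
    return(list(coverage = 0, records = NULL,
                misassembled = data.frame(name = character(0),
                                          length = integer(0))))
  # N runs (scaffold gaps) break k-mer anchoring but are not errors;
  # similarity is computed on the gap-free segments, weighted by length
  maps <- eval_map(recs, reference, as.integer(k), 3L, as.integer(band))
  G <- nchar(reference)
  covered <- logical(G)
  tab <- data.frame(name = names(recs), length = nchar(recs),
                    start = NA_integer_, strand = NA_character_,
                    similarity = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    tab$similarity[i] <- m$similarity
    if (!is.na(m$start)) {
      tab$start[i] <- m$start + 1L
      tab$strand[i] <- m$strand
    }
    iv <- m$intervals
    if (nrow(iv)) for (r in seq_len(nrow(iv)))
      covered[(iv[r, 1L] + 1L):iv[r, 2L]] <- TRUE
  }
  tab$misassembled <- tab$similarity < min_similarity
  list(coverage = mean(covered),
       records = tab,
       misassembled = tab[tab$misassembled, c("name", "length",
                                              "similarity")])
}

assembly_records <- function(assembly) {
  if (inherits(assembly, "assembly")) assembly <- assembly$contigs
  if (inherits(assembly, "scaffolds")) assembly <- assembly$sequences
  recs <- unlist(assembly)
  if (is.null(names(recs)) && length(recs))
    names(recs) <- sprintf("record_%d", seq_along(recs))
  recs
}

#' Branch-decision ledger
#'
#' Cross-tabulates a labelled branch trace into the four outcome classes
#' (correct/incorrect extension, correct/incorrect stop), with a
#' look-ahead sub-ledger split into sequencing-error checks and
#' short-repeat checks.
#'
#' @param trace labelled trace from [label_branches()] (or an unlabelled
#'   trace plus `truth`).
#' @param truth optional truth sequence; when given the trace is labelled
#'   first.
#' @return Object of class `branch_ledger`: list of `overall` counts,
#'   `rates`, and `lookahead` (per-stage correct/incorrect navigations).
#' @export
tally_branches <- function(trace, truth = NULL) {
  if (!is.null(truth)) trace <- label_branches(trace, truth)
  stopifnot("outcome_class" %in% names(trace))
  lv <- c("correct_extension", "incorrect_extension",
          "correct_stop", "incorrect_stop")
  labelled <- trace[!is.na(trace$outcome_class), , drop = FALSE]
  overall <- table(factor(labelled$outcome_class, levels = lv))
  la <- labelled[grepl("^lookahead", labelled$stage), , drop = FALSE]
  la_split <- lapply(split(la, sub("^lookahead_", "", la$stage)),
                     function(d) {
    correct <- d$outcome_class %in% c("correct_extension", "correct_stop")
    c(correct = sum(correct), incorrect = sum(!correct),
      total = nrow(d))
  })
  n <- sum(overall)
  structure(list(
    overall = overall,
    rates = if (n > 0) overall / n else overall,
    n = n,
    n_skipped = sum(is.na(trace$outcome_class)),
    lookahead = la_split), class = "branch_ledger")
}

#' @export
print.branch_ledger <- function(x, ...) {
  cat("branch ledger (", x$n, " branches, ", x$n_skipped, " skipped):\n",
      sep = "")
  for (i in seq_along(x$overall))
    cat(sprintf("  %-20s %6d (%5.2f%%)\n", names(x$overall)[i],
                x$overall[i], 100 * x$rates[i]))
  if (length(x$lookahead)) {
    cat("  look-ahead navigations:\n")
    for (nm in names(x$lookahead)) {
      v <- x$lookahead[[nm]]
      cat(sprintf("    %-8s correct %d / %d\n", nm, v["correct"],
                  v["total"]))
    }
  }
  invisible(x)
}

#' Assembly metrics against a truth sequence
#'
#' Convenience wrapper: N50, total size, reference coverage and
#' mis-assembly calls, plus the branch ledger when a trace is supplied.
#'
#' @param assembly contigs/scaffolds (vector or object).
#' @param reference truth sequence.
#' @param trace optional branch trace for the ledger.
#' @param min_len record length floor for the metrics.
#' @return List with `n50`, `total`, `n_records`, `coverage`,
#'   `misassembled`, and optionally `ledger`.
#' @export
evaluate_assembly <- function(assembly, reference, trace = NULL,
                              min_len = 100L) {
  recs <- assembly_records(assembly)
  recs <- recs[nchar(recs) >= min_len]
  mis <- call_misassemblies(recs, reference, min_len = min_len)
  out <- list(n50 = if (length(recs)) n50(nchar(recs)) else 0L,
              total = sum(nchar(recs)),
              n_records = length(recs),
              coverage = mis$coverage,
              misassembled = mis$misassembled,
              records = mis$records)
  if (!is.null(trace)) out$ledger <- tally_branches(trace, reference)
  out
}
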