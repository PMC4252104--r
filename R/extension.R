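#' Pick a seed k-mer for a new contig
#'
#' A contig starts from the 5'-terminal k-mer of an unused read whose
#' index frequency strictly exceeds the low-frequency threshold (start
#' k-mers containing sequencing errors typically occur once or twice and
#' are excluded from seeding).
#'
#' @param index a `kmer_index`.
#' @param used integer vector of read-pair ids already consumed (a read id
#'   refers to the pair; both mates are considered).
#' @param cfg an [assembly_config()].
#' @return List with `seq` (the seed k-mer), `read_id` and `mate`, or
#'   `NULL` when no eligible read remains.
#' @export
seed_contig <- function(index, used = integer(0), cfg = assembly_config()) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- index$reads
  for (i in seq_len(nrow(reads))) {
    if (reads$id[i] %in% used) next
    for (m in 1:2) {
      s <- if (m == 1L) reads$seq1[i] else reads$seq2[i]
      if (nchar(s) < cfg$k) next
      km <- substr(s, 1L, cfg$k)
      if (grepl("[^ACGT]", km)) next
      if (kmer_freq(index, km) > cfg$low_freq_threshold)
        return(list(seq = km, read_id = reads$id[i], mate = m))
    }
  }
  NULL
}

#' Align reads to a contig and build the extension pools
#'
#' Recruits every indexed read whose sampled k-mers place it on the
#' contig, verifies the placement by direct sequence comparison (at least
#' 90% of the overlapped bases must match and overall similarity must
#' reach the acceptance threshold), and splits the accepted reads into the
#' two pools used for extension: pool 1 holds reads partially aligned at
#' the extending 3' end (each contributes a candidate next base), pool 2
#' holds fully aligned reads whose mates can support candidates at a
#' compatible insert distance.  Reads failing the test are left available
#' for other genome regions.
#'
#' @param contig DNA string (length >= k).
#' @param index a `kmer_index`.
#' @param cfg an [assembly_config()].
#' @param insert optional insert model `list(mean, sd, n)`; when absent it
#'   is inferred from the fully aligned pairs found on this contig.
#' @return An object of class `read_pools`: list with `pool1`, `pool2`
#'   data frames, per-position `support` counts and the `insert` model.
#' @export
align_candidates <- function(contig, index, cfg = assembly_config(),
                             insert = NULL) {
  stopifnot(inherits(index, "kmer_index"), nchar(contig) >= cfg$k)
  res <- eng_probe(index$ptr, as.character(contig), cfg_for_engine(cfg),
                   insert_or_null(insert))
  res <- structure(res, class = "read_pools")
  attr(res, "read_len") <- max(nchar(c(index$reads$seq1, index$reads$seq2)))
  res
}

insert_or_null <- function(insert) {
  if (is.null(insert)) list(mean = 0, sd = 0, n = NULL)
  else list(mean = as.numeric(insert$mean), sd = as.numeric(insert$sd),
            n = as.integer(insert$n))
}

#' @export
print.read_pools <- function(x, ...) {
  cat("read_pools: pool1 =", nrow(x$pool1), "partial,  pool2 =",
      nrow(x$pool2), "full;  insert", round(x$insert$mean, 1), "+/-",
      round(x$insert$sd, 1), "(n =", x$insert$n, ")\n")
  invisible(x)
}

#' Tally candidate next bases from the read pools
#'
#' In paired mode only pool-1 reads whose mates sit fully aligned in
#' pool 2 at a compatible insert distance are counted; in single mode a
#' read votes only if its aligned span with the contig reaches the
#' overlap threshold `O`.
#'
#' @param pools a `read_pools` from [align_candidates()].
#' @param mode `"paired"` or `"single"`.
#' @param O single-end overlap threshold in bp (ignored in paired mode).
#' @return Named integer vector of counts over A, C, G, T.
#' @export
tally_candidates <- function(pools, mode = c("paired", "single"), O = 0L) {
  mode <- match.arg(mode)
  p1 <- pools$pool1
  keep <- if (mode == "paired") p1$paired_support & p1$strand == "-"
          else p1$overlap >= O
  tab <- table(factor(p1$next_base[keep], levels = c("A", "C", "G", "T")))
  out <- as.integer(tab)
  names(out) <- c("A", "C", "G", "T")
  out
}

#' One extension decision at the 3' end of a contig
#'
#' Applies the full decision cascade: the paired-end tally first (when the
#' insert model is established and the contig is long enough to place
#' mates), then single-end tallies swept from `O_max` down to `O_min`
#' while no overlap of the current size exists.  Unanimous or
#' clear-majority support extends; a branch is handed to the navigator;
#' no support at any O is a coverage gap and stops.
#'
#' @inheritParams align_candidates
#' @param model a navigator model list as returned by [train_navigator()]
#'   wrapped in `list(single = , paired = )`, or `NULL` for the built-in
#'   heuristic.
#' @return List with `action` (`"extend"`, `"stop"` or
#'   `"low_confidence"`), `base`, `mode`, and for branches the feature
#'   vector and tally.
#' @export
extend_step <- function(contig, index, cfg = assembly_config(),
                        model = NULL, insert = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  eng_step(index$ptr, as.character(contig), cfg_for_engine(cfg),
           model_for_engine(model, cfg), insert_or_null(insert))
}

#' Accept or reject a read against an extension path
#'
#' A read is assembled only when its similarity with the path over their
#' aligned span reaches the acceptance threshold and no mismatch cluster
#' (bubble) spans more than `O_min` bases.  Reads whose erroneous tails
#' would create short dead ends are rejected here but stay available for
#' other regions.
#'
#' @param read read sequence (aligned end-anchored to `path`).
#' @param path contig or extracted path sequence the read is compared to.
#' @param cfg an [assembly_config()].
#' @return List with `accept` (logical) and `class` (`"clean"`,
#'   `"bubble"` or `"dead_end_reject"`), plus mismatch counts.
#' @examples
#' cfg <- assembly_config()
#' read_accept("ACGTACGTAC", "ACGTACGTACGGG", cfg)$class  # clean
#' @export
read_accept <- function(read, path, cfg = assembly_config()) {
  read <- as.character(read)
  path <- as.character(path)
  ov <- min(nchar(read), nchar(path))
  a <- strsplit(substr(read, 1L, ov), "")[[1]]
  b <- strsplit(substr(path, 1L, ov), "")[[1]]
  mism <- a != b
  mm <- sum(mism)
  sim <- 1 - mm / ov
  runs <- rle(mism)
  maxrun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  trailing <- if (mism[ov]) runs$lengths[length(runs$lengths)] else 0L
  accept <- sim >= cfg$min_similarity && sim >= cfg$min_align_frac &&
    maxrun <= cfg$O_min
  cls <- if (accept && mm == 0L) "clean"
         else if (accept) "bubble"
         else if (trailing > 0L && trailing < nchar(read)) "dead_end_reject"
         else "reject"
  list(accept = accept, class = cls, mismatches = mm, similarity = sim,
       max_mismatch_run = maxrun)
}

#' Update the insert-size model from fully aligned pairs
#'
#' The insert size of a pair is the span between the two mates' outer 5'
#' ends.  Only pairs with both ends fully aligned to the contig in inward
#' orientation (forward mate upstream of the reverse mate) contribute;
#' mean and standard deviation are the sample statistics (n - 1).
#'
#' @param contig the contig the pools were computed on.
#' @param pools a `read_pools` from [align_candidates()].
#' @param insert optional previous model to which the new observations are
#'   pooled (`list(mean, sd, n)`).
#' @return Updated `list(mean, sd, n)`.
#' @export
update_insert_model <- function(contig, pools, insert = NULL) {
  p2 <- pools$pool2
  rl <- attr(pools, "read_len")
  if (is.null(rl)) stop("pass pools from align_candidates()")
  spans <- numeric(0)
  if (nrow(p2) >= 2L) {
    for (id in unique(p2$read_id[duplicated(p2$read_id)])) {
      rec <- p2[p2$read_id == id, ]
      if (nrow(rec) != 2L) next
      fwd <- rec[rec$strand == "+", ]
      rev <- rec[rec$strand == "-", ]
      if (nrow(fwd) != 1L || nrow(rev) != 1L) next
      if (fwd$off > rev$off) next
      spans <- c(spans, rev$off + rl - fwd$off)
    }
  }
  merge_insert(insert, spans)
}

merge_insert <- function(insert, spans) {
  if (is.null(insert) || is.null(insert$n) || insert$n == 0) {
    n <- length(spans)
    if (n < 2L) stop("need at least 2 fully aligned inward pairs")
    return(list(mean = mean(spans), sd = sd(spans), n = n))
  }
  n0 <- insert$n
  s0 <- insert$mean * n0
  ss0 <- (if (n0 > 1) insert$sd^2 * (n0 - 1) else 0) + insert$mean^2 * n0
  n <- n0 + length(spans)
  s <- s0 + sum(spans)
  ss <- ss0 + sum(spans^2)
  m <- s / n
  v <- if (n > 1) (ss - s^2 / n) / (n - 1) else 0
  list(mean = m, sd = sqrt(max(v, 0)), n = n)
}

#' Assemble reads into contigs
#'
#' Phase 1 of the assembler.  Contigs are seeded from terminal k-mers of
#' unused reads, extended base by base at the 3' end, then
#' reverse-complemented and extended again so both directions share one
#' code path.  Reads are consumed (marked used) when they become fully
#' aligned; contigs shorter than `min_contig_len` are discarded.  Every
#' branch decision is recorded in the returned trace, which is what the
#' navigator trains on and what [label_branches()] scores against a known
#' truth sequence.
#'
#' @param reads read-pair table, `simulated_reads`, or a prebuilt
#'   `kmer_index`.
#' @param cfg an [assembly_config()].
#' @param model navigator model (see [train_navigator()]); `NULL` uses
#'   the heuristic fallback, `"default"` loads the bundled model.
#' @param insert optional insert-size prior `list(mean, sd, n)`; normally
#'   inferred on the fly.
#' @param return_records keep per-contig read alignment records.
#' @return Object of class `assembly`: list with `contigs` (named DNA
#'   vector), `trace` (branch decisions), `insert` (inferred model),
#'   `n_reads_used`, and optionally `records`.
#' @examples
#' g <- generate_genome(8000, seed = 5)
#' sim <- simulate_pairs(g, coverage = 40, seed = 5)
#' asm <- assemble_contigs(sim, assembly_config(navigation = "heuristic"))
#' nchar(asm$contigs)
#' @export
assemble_contigs <- function(reads, cfg = assembly_config(), model = NULL,
                             insert = NULL, return_records = FALSE) {
  index <- if (inherits(reads, "kmer_index")) reads
           else build_kmer_index(reads, cfg)
  set.seed(cfg$seed)
  model_list <- model_for_engine(model, cfg)
  cb <- make_lookahead_resolver(cfg)
  res <- eng_assemble(index$ptr, cfg_for_engine(cfg), model_list, cb,
                      cfg$use_lookahead, insert_or_null(insert),
                      isTRUE(return_records))
  contigs <- res$contigs
  if (length(contigs))
    names(contigs) <- sprintf("contig_%d", seq_along(contigs))
  structure(list(contigs = contigs, trace = res$trace,
                 insert = res$insert, n_reads_used = res$n_reads_used,
                 records = if (return_records) res$records,
                 cfg = cfg, index = index),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  len <- nchar(x$contigs)
  cat("assembly:", length(len), "contigs, total", sum(len), "bp, N50",
      if (length(len)) n50(len) else 0, "bp\n")
  cat("  insert model:", round(x$insert$mean, 1), "+/-",
      round(x$insert$sd, 1), "bp (n =", x$insert$n, ");",
      nrow(x$trace), "branch decisions\n")
  invisible(x)
}

# internal: build the engine's model argument
model_for_engine <- function(model, cfg) {
  if (is.character(model) && identical(model, "default"))
    model <- navigator_default()
  if (is.null(model)) return(list(margin = cfg$svm_margin))
  out <- list(margin = cfg$svm_margin)
  for (mode in c("paired", "single")) {
    m <- model[[mode]]
    if (!is.null(m))
      out[[mode]] <- list(sv = m$sv, coef = m$coef, rho = m$rho,
                          margin = m$margin, center = m$center,
                          scale = m$scale)
  }
  out
}
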