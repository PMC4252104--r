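#' Extract candidate forward paths at a branch
#'
#' For every candidate base with read support at the current extension
#' point, a path is grown greedily past the branch: the supporting reads
#' vote base by base, new reads are recruited from the index as the path
#' terminus advances, and a path ends at a tie, at read exhaustion, or at
#' the look-ahead horizon (insert mean plus `insert_sd_mult` standard
#' deviations -- beyond the insert size paired reads carry no signal).
#'
#' @param contig DNA string ending at the branch.
#' @param index a `kmer_index`.
#' @param cfg an [assembly_config()].
#' @param insert optional insert model `list(mean, sd, n)`.
#' @return List of `candidate_path` objects, each with `seq` (bases past
#'   the branch), `first_base`, `reads` (supporting reads with offsets
#'   relative to the branch and oriented sequences),
#'   `mismatches_vs_contig` (best back-alignment of the path onto the
#'   contig's assembled end) and `pair_distances` (implied insert spans of
#'   pairs bridging path and contig).
#' @export
extract_paths <- function(contig, index, cfg = assembly_config(),
                          insert = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  paths <- eng_paths(index$ptr, as.character(contig), cfg_for_engine(cfg),
                     insert_or_null(insert))
  lapply(paths, function(p) structure(p, class = "candidate_path"))
}

# per-column votes over the region where at least two paths are defined;
# shorter path tails are ignored.  Votes are deduplicated per (read,
# offset) so a read recruited by several paths counts once.
path_columns <- function(paths) {
  lens <- vapply(paths, function(p) nchar(p$seq), 1L)
  ncol <- sort(lens, decreasing = TRUE)[2]
  if (is.na(ncol) || ncol < 1L) return(NULL)
  col <- integer(0); base <- character(0); seen <- character(0)
  for (p in paths) {
    rd <- p$reads
    for (i in seq_len(nrow(rd))) {
      key <- paste0(rd$read_id[i], "@", rd$off[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      L <- nchar(rd$seq[i]); off <- rd$off[i]
      c0 <- max(1L, off + 1L); c1 <- min(ncol, off + L)
      if (c0 > c1) next
      cols <- c0:c1
      col <- c(col, cols)
      base <- c(base, substring(rd$seq[i], cols - off, cols - off))
    }
  }
  if (!length(col)) return(NULL)
  list(col = col, base = base, ncol = ncol)
}

#' Classify a branch from its candidate paths
#'
#' Computes, per column, the ratio of the majority nucleotide over all
#' path-supporting reads.  A column whose majority ratio falls below
#' `path_majority` counts as incorrect; fewer than `max_bad_positions`
#' such columns means the disagreement looks like scattered sequencing
#' error and extension continues with the majority base, otherwise the
#' branch must be checked for short tandem repeats.
#'
#' @param paths list of `candidate_path` objects (>= 2).
#' @param cfg an [assembly_config()].
#' @return List with `verdict` (`"CONTINUE"` or `"CHECK_REPEATS"`),
#'   `base` (majority base at the branch column, for CONTINUE) and
#'   `bad_columns`.
#' @export
consensus_verdict <- function(paths, cfg = assembly_config()) {
  stopifnot(length(paths) >= 2L)
  pc <- path_columns(paths)
  if (is.null(pc))
    return(list(verdict = "CHECK_REPEATS", base = NA_character_,
                bad_columns = NA_integer_))
  bad <- 0L
  maj1 <- NA_character_
  for (cc in sort(unique(pc$col))) {
    tt <- table(pc$base[pc$col == cc])
    if (cc == 1L) maj1 <- names(which.max(tt))
    if (max(tt) / sum(tt) < cfg$path_majority) bad <- bad + 1L
  }
  if (bad < cfg$max_bad_positions)
    list(verdict = "CONTINUE", base = maj1, bad_columns = bad)
  else
    list(verdict = "CHECK_REPEATS", base = maj1, bad_columns = bad)
}

#' Resolve a tandem-repeat branch by path overlap
#'
#' When the suffix of one path overlaps the prefix of another by strictly
#' more than `min_path_overlap` bases, the two paths trace consecutive
#' copies of a nearby tandem repeat: they are merged and extension
#' continues along the leading path (its reads re-anchor on the later
#' copy as the contig reaches it).  Inside a periodic array the overlap
#' alone can hold in both orders; the phase is then decided by the pairs
#' bridging path and contig -- the leading path is the candidate whose
#' mean implied insert span sits closest to the insert model mean.
#' Without any overlap the copies come from distant genome regions and
#' extension stops.
#'
#' @inheritParams consensus_verdict
#' @param insert insert model `list(mean, sd, n)`; used to arbitrate
#'   between mutually overlapping (phase-ambiguous) path orders.
#' @return List with `action` (`"MERGE"` or `"STOP"`), the leading path
#'   index `i`, trailing index `j` and `overlap` length.
#' @export
resolve_tandem <- function(paths, insert = NULL, cfg = assembly_config()) {
  stopifnot(length(paths) >= 2L)
  cand <- NULL
  for (i in seq_along(paths)) for (j in seq_along(paths)) {
    if (i == j) next
    ov <- cpp_best_overlap(paths[[i]]$seq, paths[[j]]$seq,
                           min(nchar(paths[[i]]$seq),
                               nchar(paths[[j]]$seq)),
                           0.1)
    # the trailing copy must start strictly inside the leading path;
    # shift ~ 0 means the paths converge (sequencing-error bubble, not
    # two repeat copies)
    shift <- nchar(paths[[i]]$seq) - ov$len
    if (ov$len > cfg$min_path_overlap && shift > cfg$min_path_overlap)
      cand <- rbind(cand, data.frame(i = i, j = j, overlap = ov$len))
  }
  if (is.null(cand)) return(list(action = "STOP", i = NA, j = NA,
                                 overlap = 0L))
  # the leading path is the one with the longest suffix->prefix match
  # (smallest phase shift); pair-distance deviation breaks exact ties
  pick <- which(cand$overlap == max(cand$overlap))
  if (length(pick) > 1L) {
    dev_of <- function(ix) {
      pd <- paths[[ix]]$pair_distances
      if (!length(pd) || is.null(insert$n) || !insert$n) return(Inf)
      abs(mean(pd) - insert$mean)
    }
    devs <- vapply(cand$i[pick], dev_of, 1)
    pick <- pick[which.min(devs)]
  }
  list(action = "MERGE", i = cand$i[pick], j = cand$j[pick],
       overlap = cand$overlap[pick])
}

#' Remove spurious candidate paths
#'
#' A path is spurious when it disagrees with the local contig sequence at
#' more than two bases *and* its bridging pairs imply an insert distance
#' deviating from the model mean by more than `insert_sd_mult` standard
#' deviations -- both conditions together indicate a repeat copy from a
#' distant genome region.  Removed paths release their reads back to the
#' unused pool.
#'
#' @inheritParams consensus_verdict
#' @param insert insert model `list(mean, sd, n)`.
#' @return List with `paths` (the retained subset) and `released`
#'   (read ids of removed paths).
#' @export
prune_spurious_paths <- function(paths, insert, cfg = assembly_config()) {
  keep <- vapply(paths, function(p) {
    dev <- if (length(p$pair_distances) && !is.null(insert$n) &&
               insert$n > 1)
      abs(mean(p$pair_distances) - insert$mean)
    else 0
    !(p$mismatches_vs_contig > 2L && dev > cfg$insert_sd_mult * insert$sd)
  }, TRUE)
  released <- unlist(lapply(paths[!keep], function(p) p$reads$read_id))
  list(paths = paths[keep], released = unique(released))
}

# internal: do all paths describe the same continuation (pairwise
# overlap at shift <= min_path_overlap with tolerant matching)?
paths_converge <- function(paths, cfg) {
  for (i in seq_along(paths)) for (j in seq_along(paths)) {
    if (i >= j) next
    ov <- cpp_best_overlap(paths[[i]]$seq, paths[[j]]$seq,
                           min(nchar(paths[[i]]$seq),
                               nchar(paths[[j]]$seq)), 0.1)
    if (nchar(paths[[i]]$seq) - ov$len > cfg$min_path_overlap)
      return(FALSE)
  }
  TRUE
}

# internal: the resolver closure handed to the extension engine for
# low-confidence branches.  Order: consensus verdict (sequencing error)
# first, then tandem-overlap merge, then spurious-path pruning; stop when
# more than one distinct continuation survives.
make_lookahead_resolver <- function(cfg) {
  function(paths, ins) {
    if (length(paths) == 0L)
      return(list(action = "stop", base = "", stage = "error"))
    paths <- lapply(paths, function(p) structure(p,
                                                 class = "candidate_path"))
    if (length(paths) == 1L)
      return(list(action = "extend", base = paths[[1]]$first_base,
                  stage = "error"))
    # paths that die before one read length are dead ends (reads with
    # erroneous tails); eliminating them resolves the branch implicitly
    rl <- if (!is.null(ins$read_len)) ins$read_len else 100L
    dead <- vapply(paths, function(p)
      isTRUE(p$died_early) && nchar(p$seq) < rl, TRUE)
    if (any(dead) && sum(!dead) >= 1L) {
      paths <- paths[!dead]
      if (length(paths) == 1L)
        return(list(action = "extend", base = paths[[1]]$first_base,
                    stage = "error"))
    }
    v <- consensus_verdict(paths, cfg)
    if (v$verdict == "CONTINUE" && !is.na(v$base))
      return(list(action = "extend", base = v$base, stage = "error"))
    # a decisive majority at the branch column itself settles this base;
    # path disagreement further ahead belongs to a later decision point
    pc <- path_columns(paths)
    if (!is.null(pc)) {
      t1 <- table(pc$base[pc$col == 1L])
      if (length(t1) && max(t1) / sum(t1) >= cfg$path_majority)
        return(list(action = "extend", base = names(which.max(t1)),
                    stage = "error"))
    }
    t <- resolve_tandem(paths, ins, cfg)
    if (t$action == "MERGE")
      return(list(action = "extend", base = paths[[t$i]]$first_base,
                  stage = "repeat"))
    # no two-copy configuration: paths that converge are one continuation
    # sampled with noise; take the branch-column majority
    if (paths_converge(paths, cfg) && !is.na(v$base))
      return(list(action = "extend", base = v$base, stage = "error"))
    pr <- prune_spurious_paths(paths, ins, cfg)
    if (length(pr$paths) == 1L)
      return(list(action = "extend", base = pr$paths[[1]]$first_base,
                  stage = "repeat"))
    list(action = "stop", base = "", stage = "repeat")
  }
}
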