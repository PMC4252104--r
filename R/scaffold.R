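# Phase 2: order and orient contigs into scaffolds from paired-end links.
#
# Placement convention: an edge between contigs A and B (A = smaller index)
# stores a 4-weight quaternion over the relative configurations of A
# placed before B: (A+,B+), (A+,B-), (A-,B+), (A-,B-).  A pair with one
# read on each contig determines the placement uniquely because both reads
# point toward the junction: A's orientation equals the strand of its
# read, B's orientation is the flip of its read's strand.

PLACEMENTS <- c("++", "+-", "-+", "--")

flip_o <- function(o) ifelse(o == "+", "-", "+")

#' Build the scaffold graph from contig linking regions
#'
#' Re-aligns all reads to the contigs, keeps only reads that align fully
#' and uniquely (one locus across the whole assembly) within a linking
#' region (the terminal `linking_region` bp of a contig), and turns every
#' pair with its two mates on different contigs into a placement vote.
#' Each edge carries the placement quaternion plus the per-pair distances
#' to the gap margins needed for gap estimation.
#'
#' @param contigs named character vector of contigs (or an `assembly`).
#' @param index `kmer_index` over the read set (or a read-pair table).
#' @param cfg an [assembly_config()].
#' @return Object of class `scaffold_graph`.
#' @export
build_scaffold_graph <- function(contigs, index, cfg = assembly_config()) {
  if (inherits(contigs, "assembly")) {
    if (is.null(index)) index <- contigs$index
    contigs <- contigs$contigs
  }
  if (!inherits(index, "kmer_index")) index <- build_kmer_index(index, cfg)
  stopifnot(length(contigs) >= 1L)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig_%d", seq_along(contigs))
  lens <- nchar(contigs)
  rl <- max(nchar(c(index$reads$seq1, index$reads$seq2)))

  alns <- lapply(seq_along(contigs), function(ci) {
    a <- aln_full(index$ptr, contigs[[ci]], cfg_for_engine(cfg))
    if (nrow(a)) a$contig <- ci
    a
  })
  aln <- do.call(rbind, alns[vapply(alns, nrow, 1L) > 0L])
  if (is.null(aln) || nrow(aln) == 0L)
    return(empty_scaffold_graph(contigs, lens, cfg))

  # uniqueness: a read (pair id + mate) aligning at more than one locus
  # anywhere contributes nothing
  key <- paste(aln$read_id, aln$mate)
  aln <- aln[!(key %in% key[duplicated(key)]), , drop = FALSE]

  # linking-region membership (either end)
  lr <- cfg$linking_region
  inlr <- aln$off < lr | (aln$off + rl) > (lens[aln$contig] - lr)
  aln <- aln[inlr, , drop = FALSE]

  m1 <- aln[aln$mate == 1L, ]
  m2 <- aln[aln$mate == 2L, ]
  j <- merge(m1, m2, by = "read_id", suffixes = c("_1", "_2"))
  j <- j[j$contig_1 != j$contig_2, , drop = FALSE]

  edges <- list()
  if (nrow(j)) {
    for (r in seq_len(nrow(j))) {
      c1 <- j$contig_1[r]; c2 <- j$contig_2[r]
      if (c1 < c2) {
        A <- c1; B <- c2
        sA <- j$strand_1[r]; offA <- j$off_1[r]
        sB <- j$strand_2[r]; offB <- j$off_2[r]
      } else {
        A <- c2; B <- c1
        sA <- j$strand_2[r]; offA <- j$off_2[r]
        sB <- j$strand_1[r]; offB <- j$off_1[r]
      }
      oA <- sA
      oB <- flip_o(sB)
      d_a <- if (oA == "+") lens[A] - offA else offA + rl
      d_b <- if (oB == "+") offB + rl else lens[B] - offB
      ek <- paste0(A, "|", B)
      pl <- paste0(oA, oB)
      if (is.null(edges[[ek]]))
        edges[[ek]] <- list(A = A, B = B,
                            w = setNames(integer(4L), PLACEMENTS),
                            d = setNames(vector("list", 4L), PLACEMENTS))
      edges[[ek]]$w[pl] <- edges[[ek]]$w[pl] + 1L
      edges[[ek]]$d[[pl]] <- rbind(edges[[ek]]$d[[pl]], c(d_a, d_b))
    }
  }
  structure(list(contigs = contigs, lens = lens, edges = edges,
                 linking_region = cfg$linking_region, read_len = rl),
            class = "scaffold_graph")
}

empty_scaffold_graph <- function(contigs, lens, cfg) {
  structure(list(contigs = contigs, lens = lens, edges = list(),
                 linking_region = cfg$linking_region, read_len = NA_integer_),
            class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat("scaffold_graph:", length(x$contigs), "contigs,",
      length(x$edges), "edges\n")
  invisible(x)
}

# candidate neighbours to the right of contig `C` carrying orientation
# `o`: data.frame(contig, orientation, weight, edge key, placement key)
right_candidates <- function(graph, C, o, used) {
  out <- NULL
  for (ek in names(graph$edges)) {
    e <- graph$edges[[ek]]
    if (e$A == C) {
      D <- e$B
      if (used[D]) next
      for (oD in c("+", "-")) {
        pl <- paste0(o, oD)
        w <- e$w[pl]
        if (w > 0L)
          out <- rbind(out, data.frame(contig = D, orientation = oD,
                                       weight = w, edge = ek,
                                       placement = pl,
                                       stringsAsFactors = FALSE))
      }
    } else if (e$B == C) {
      D <- e$A
      if (used[D]) next
      # stored placements are D-before-C; C-before-D with C at `o`
      # corresponds to (oD', flip(o)) reversed: need stored oC == flip(o),
      # and D's right-hand orientation is flip(stored oD)
      for (oD_stored in c("+", "-")) {
        pl <- paste0(oD_stored, flip_o(o))
        w <- e$w[pl]
        if (w > 0L)
          out <- rbind(out, data.frame(contig = D,
                                       orientation = flip_o(oD_stored),
                                       weight = w, edge = ek,
                                       placement = pl,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Greedily link contigs into scaffolds
#'
#' Seeds from the longest contig at least as long as the linking region,
#' then extends to the right and (after reversing the growing scaffold)
#' to the left.  A neighbour is accepted only when its best placement
#' weight reaches `min_link_pairs` supporting pairs and is at least twice
#' the weight of any competing candidate; undifferentiated alternatives
#' terminate the extension.  Contigs shorter than the linking region that
#' remain unlinked become singleton scaffolds.
#'
#' @param graph a `scaffold_graph`.
#' @param cfg an [assembly_config()].
#' @param min_link_pairs minimum supporting pairs for a link.
#' @return List of scaffolds; each is a `data.frame` with columns
#'   `contig` (index), `name`, `orientation`, and per-junction `gap`
#'   estimate and `n_pairs` (`NA` for the first row).
#' @export
greedy_link <- function(graph, cfg = assembly_config(),
                        min_link_pairs = 3L) {
  n <- length(graph$contigs)
  used <- rep(FALSE, n)
  scaffolds <- list()
  repeat {
    eligible <- which(!used & graph$lens >= graph$linking_region)
    if (!length(eligible)) break
    seed <- eligible[which.max(graph$lens[eligible])]
    used[seed] <- TRUE
    chain <- data.frame(contig = seed, orientation = "+",
                        gap = NA_real_, n_pairs = NA_integer_,
                        stringsAsFactors = FALSE)
    for (side in 1:2) {
      repeat {
        tailrow <- chain[nrow(chain), ]
        cand <- right_candidates(graph, tailrow$contig,
                                 tailrow$orientation, used)
        if (is.null(cand) || nrow(cand) == 0L) break
        cand <- cand[order(-cand$weight), , drop = FALSE]
        best <- cand[1L, ]
        second <- if (nrow(cand) > 1L) cand$weight[2L] else 0L
        if (best$weight < min_link_pairs || best$weight < 2L * second)
          break  # multiple candidates undifferentiated
        e <- graph$edges[[best$edge]]
        d <- e$d[[best$placement]]
        used[best$contig] <- TRUE
        chain <- rbind(chain,
                       data.frame(contig = best$contig,
                                  orientation = best$orientation,
                                  gap = NA_real_,
                                  n_pairs = best$weight,
                                  stringsAsFactors = FALSE))
        chain$gap[nrow(chain)] <- mean_gap_from_d(d, graph)
      }
      # reverse the scaffold and extend the other end the same way
      chain <- reverse_chain(chain)
    }
    scaffolds[[length(scaffolds) + 1L]] <- chain
  }
  for (ci in which(!used))
    scaffolds[[length(scaffolds) + 1L]] <-
      data.frame(contig = ci, orientation = "+", gap = NA_real_,
                 n_pairs = NA_integer_, stringsAsFactors = FALSE)
  for (s in seq_along(scaffolds))
    scaffolds[[s]]$name <- names(graph$contigs)[scaffolds[[s]]$contig]
  scaffolds
}

# placeholder: filled in by scaffold_contigs once the insert model is
# known; greedy_link stores the per-junction (d_a, d_b) means instead
mean_gap_from_d <- function(d, graph) {
  attr_ins <- attr(graph, "insert")
  if (is.null(attr_ins)) return(mean(-d[, 1L] - d[, 2L]))
  mean(attr_ins$mean - d[, 1L] - d[, 2L])
}

reverse_chain <- function(chain) {
  n <- nrow(chain)
  if (n == 1L) {
    chain$orientation <- flip_o(chain$orientation)
    return(chain)
  }
  out <- chain[n:1L, , drop = FALSE]
  out$orientation <- flip_o(out$orientation)
  # junction annotations ride on the right-hand contig of each junction
  gaps <- chain$gap[n:2L]
  np <- chain$n_pairs[n:2L]
  out$gap <- c(NA_real_, gaps)
  out$n_pairs <- c(NA_integer_, np)
  rownames(out) <- NULL
  out
}

#' Estimate the gap between two linked contigs
#'
#' For each bridging pair the gap is the insert mean minus the distances
#' of the two reads' 5' ends to their contigs' gap margins; the final
#' estimate averages over the pairs.  Negative estimates indicate
#' overlapping contigs.
#'
#' @param pairs `data.frame` (or matrix) with columns `d_a`, `d_b`.
#' @param insert insert model `list(mean, sd, n)`.
#' @return Estimated gap size in bp (signed).
#' @examples
#' estimate_gap(data.frame(d_a = 150, d_b = 150),
#'              list(mean = 370, sd = 56, n = 100))  # 70
#' @export
estimate_gap <- function(pairs, insert) {
  pairs <- as.data.frame(pairs)
  if (!all(c("d_a", "d_b") %in% names(pairs)))
    names(pairs)[1:2] <- c("d_a", "d_b")
  if (nrow(pairs) == 0L) stop("no bridging pairs")
  mean(insert$mean - pairs$d_a - pairs$d_b)
}

#' Resolve one scaffold junction
#'
#' Large positive gap estimates keep the junction gapped.  Estimates that
#' are negative or within estimator noise (one insert standard deviation)
#' trigger a pairwise end alignment of the two oriented contigs; an
#' overlap longer than `min_contig_merge_overlap` that agrees with the
#' estimate (within `max(5, insert sd)`) merges the junction, with the
#' overlap taken once.  Otherwise the junction stays gapped with an N-run
#' of the estimated size (at least one N).
#'
#' @param left,right oriented contig sequences flanking the junction.
#' @param gap_estimate estimated gap in bp (signed).
#' @param insert insert model `list(mean, sd, n)`.
#' @param cfg an [assembly_config()].
#' @return List with `status` (`"merged"` or `"gapped"`), `overlap`,
#'   `gap` (N-run length for gapped junctions).
#' @export
resolve_junction <- function(left, right, gap_estimate, insert,
                             cfg = assembly_config()) {
  sdi <- max(insert$sd, 1)
  if (!is.finite(gap_estimate)) gap_estimate <- 0
  if (gap_estimate > sdi)
    return(list(status = "gapped", overlap = 0L,
                gap = max(1L, as.integer(round(gap_estimate)))))
  w <- as.integer(min(min(nchar(left), nchar(right)),
                      max(40, ceiling(-gap_estimate + 3 * sdi))))
  tail <- substr(left, nchar(left) - w + 1L, nchar(left))
  head <- substr(right, 1L, w)
  ov <- cpp_best_overlap(tail, head, w, 0.05)
  if (ov$len > cfg$min_contig_merge_overlap &&
      abs(ov$len - (-gap_estimate)) <= max(5, sdi))
    return(list(status = "merged", overlap = ov$len, gap = 0L))
  list(status = "gapped", overlap = 0L,
       gap = max(1L, as.integer(round(gap_estimate))))
}

#' Fill scaffold gaps by local assembly
#'
#' For each gapped junction, reads whose mates anchor uniquely on the
#' flanking contig ends (pointing into the gap) are collected and the
#' phase-1 extension engine is run on that read subset from the left
#' flank into the gap (and from the right flank when the left side does
#' not close it).  A gap is closed when the local extension reaches the
#' opposite flank with an overlap of at least `O_min` bases; residual
#' gaps keep their N-run.
#'
#' @param scaffolds output of [greedy_link()].
#' @param graph the `scaffold_graph`.
#' @param index `kmer_index` over the full read set.
#' @param insert insert model `list(mean, sd, n)`.
#' @param cfg an [assembly_config()].
#' @param junctions resolved junction table (internal).
#' @return The junction table with `status` upgraded to `"filled"` and
#'   the fill sequence attached where local assembly closed the gap.
#' @keywords internal
fill_gap_junction <- function(left, right, gap, index, insert, cfg) {
  rl <- max(nchar(c(index$reads$seq1, index$reads$seq2)))
  flank <- as.integer(min(nchar(left),
                          round(insert$mean + 3 * max(insert$sd, 1))))
  fl <- substr(left, nchar(left) - flank + 1L, nchar(left))
  fr <- substr(right, 1L, min(nchar(right),
                              as.integer(round(insert$mean +
                                               3 * max(insert$sd, 1)))))
  sub <- gap_read_subset(fl, fr, index, cfg)
  if (is.null(sub)) return(NULL)
  max_bases <- as.integer(gap + 3 * max(insert$sd, 1) + 2L * rl)
  for (side in 1:2) {
    if (side == 1L) { from <- fl; to <- fr }
    else { from <- revcomp_dna(fr); to <- revcomp_dna(fl) }
    ext <- eng_extend_from(sub$ptr, from, cfg_for_engine(cfg),
                           list(margin = cfg$svm_margin),
                           make_lookahead_resolver(cfg), cfg$use_lookahead,
                           insert_or_null(insert), max_bases)
    if (ext$added <= 0L) next
    ov <- cpp_best_overlap(ext$seq, to,
                           min(nchar(ext$seq), nchar(to)), 0.05)
    if (ov$len >= cfg$O_min) {
      fill_len <- nchar(ext$seq) - ov$len - nchar(from)
      if (fill_len < 0L)
        return(list(status = "merged", overlap = -fill_len, fill = ""))
      fill <- substr(ext$seq, nchar(from) + 1L, nchar(ext$seq) - ov$len)
      if (side == 2L) fill <- revcomp_dna(fill)
      return(list(status = "filled", overlap = 0L, fill = fill))
    }
  }
  NULL
}

# pairs with a unique full alignment on either flank: candidate gap reads
gap_read_subset <- function(left_flank, right_flank, index, cfg) {
  a1 <- aln_full(index$ptr, left_flank, cfg_for_engine(cfg))
  a2 <- aln_full(index$ptr, right_flank, cfg_for_engine(cfg))
  ids <- unique(c(a1$read_id, a2$read_id))
  if (length(ids) < 2L) return(NULL)
  sub <- index$reads[index$reads$id %in% ids, , drop = FALSE]
  build_kmer_index(sub, cfg)
}

#' Order, orient, merge and gap-fill contigs into scaffolds
#'
#' Runs the whole second phase: scaffold-graph construction from linking
#' regions, greedy linking with placement weights, gap estimation,
#' junction resolution (merge on agreeing overlap), local-assembly gap
#' filling, and sequence emission.
#'
#' @param assembly an `assembly` from [assemble_contigs()], or a named
#'   character vector of contigs.
#' @param index `kmer_index` of the read set (taken from the assembly if
#'   absent).
#' @param cfg an [assembly_config()].
#' @param insert insert model; taken from the assembly when available.
#' @param fill_gaps run local assembly on gapped junctions.
#' @param min_link_pairs minimum supporting pairs for a link.
#' @return Object of class `scaffolds`: list with `sequences` (named DNA
#'   vector), `junctions` (per-junction table) and `chains` (contig
#'   order/orientation per scaffold).
#' @export
scaffold_contigs <- function(assembly, index = NULL,
                             cfg = assembly_config(), insert = NULL,
                             fill_gaps = TRUE, min_link_pairs = 3L) {
  if (inherits(assembly, "assembly")) {
    contigs <- assembly$contigs
    if (is.null(index)) index <- assembly$index
    if (is.null(insert)) insert <- assembly$insert
  } else contigs <- assembly
  if (is.null(insert) || is.null(insert$n) || insert$n < 2L)
    stop("an insert-size model is required for scaffolding")
  if (!inherits(index, "kmer_index")) index <- build_kmer_index(index, cfg)
  graph <- build_scaffold_graph(contigs, index, cfg)
  attr(graph, "insert") <- insert
  chains <- greedy_link(graph, cfg, min_link_pairs)
  seqs <- character(0)
  jtab <- NULL
  out_chains <- list()
  for (si in seq_along(chains)) {
    ch <- chains[[si]]
    oriented <- vapply(seq_len(nrow(ch)), function(i) {
      s <- graph$contigs[[ch$contig[i]]]
      if (ch$orientation[i] == "-") revcomp_dna(s) else s
    }, "")
    seq <- oriented[1L]
    if (nrow(ch) > 1L) for (i in 2L:nrow(ch)) {
      res <- resolve_junction(seq, oriented[i], ch$gap[i], insert, cfg)
      if (res$status == "gapped" && fill_gaps) {
        fg <- fill_gap_junction(seq, oriented[i], res$gap, index, insert,
                                cfg)
        if (!is.null(fg)) res <- fg
      }
      seq <- switch(res$status,
        merged = paste0(seq, substr(oriented[i], res$overlap + 1L,
                                    nchar(oriented[i]))),
        filled = paste0(seq, res$fill, oriented[i]),
        gapped = paste0(seq, strrep("N", res$gap), oriented[i]))
      jtab <- rbind(jtab, data.frame(
        scaffold = si, left = ch$name[i - 1L], right = ch$name[i],
        orientation_left = ch$orientation[i - 1L],
        orientation_right = ch$orientation[i],
        gap_estimate = ch$gap[i], n_pairs = ch$n_pairs[i],
        status = res$status,
        overlap = res$overlap,
        stringsAsFactors = FALSE))
    }
    seqs[sprintf("scaffold_%d", si)] <- seq
    out_chains[[si]] <- ch
  }
  structure(list(sequences = seqs, junctions = jtab, chains = out_chains,
                 graph = graph),
            class = "scaffolds")
}

#' @export
print.scaffolds <- function(x, ...) {
  len <- nchar(x$sequences)
  cat("scaffolds:", length(len), "sequences, total", sum(len), "bp, N50",
      n50(len), "bp;", sum(x$junctions$status == "merged"), "merged /",
      sum(x$junctions$status == "filled"), "filled /",
      sum(x$junctions$status == "gapped"), "gapped junctions\n")
  invisible(x)
}

#' Emit scaffold sequences as FASTA
#'
#' @param scaffolds a `scaffolds` object.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
emit_scaffolds <- function(scaffolds, path) {
  write_fasta(scaffolds$sequences, path)
}
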