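#' Describe a (possibly nested) tandem-repeat array
#'
#' A repeat array is `copies` near-identical units of `unit_len` bp placed
#' adjacently, separated by random spacers of `spacer` bp.  Short tandem
#' repeats in real genomes are typically under 100 bp with adjacent copies
#' less than 100 bp apart, which is the regime the assembler's look-ahead
#' stage has to separate.  A nested spec places one copy of the inner
#' repeat inside each outer unit; inner copies beyond the number of outer
#' copies are appended to the array as standalone units, so nesting counts
#' like "A three times containing B four times containing C five times"
#' are expressible directly.
#'
#' @param unit_len length of one repeat unit in bp.
#' @param copies number of copies (>= 2).
#' @param spacer bp of random sequence between adjacent copies.
#' @param divergence per-base substitution rate applied independently to
#'   each copy (0 = identical copies).
#' @param nesting optional inner `repeat_spec`.
#' @return An object of class `repeat_spec`.
#' @examples
#' repeat_spec(60, 3, spacer = 30)
#' # File-S1-style nesting: A x3 containing B x4 containing C x5
#' repeat_spec(55, 3, 10, nesting = repeat_spec(35, 4, 8,
#'             nesting = repeat_spec(18, 5, 6)))
#' @export
repeat_spec <- function(unit_len, copies, spacer = 30L, divergence = 0,
                        nesting = NULL) {
  stopifnot(unit_len >= 1L, copies >= 2L, spacer >= 0L,
            divergence >= 0, divergence < 1,
            is.null(nesting) || inherits(nesting, "repeat_spec"))
  structure(list(unit_len = as.integer(unit_len),
                 copies = as.integer(copies),
                 spacer = as.integer(spacer),
                 divergence = as.numeric(divergence),
                 nesting = nesting),
            class = "repeat_spec")
}

# total bp of the array a spec expands to (units + spacers + extra inner
# copies, recursively)
repeat_region_len <- function(spec) {
  len <- spec$copies * spec$unit_len + (spec$copies - 1L) * spec$spacer
  placed <- spec$copies
  inner <- spec$nesting
  while (!is.null(inner)) {
    extra <- max(0L, inner$copies - placed)
    if (extra > 0L)
      len <- len + extra * (inner$unit_len + inner$spacer)
    placed <- max(placed, inner$copies)
    inner <- inner$nesting
  }
  len
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

# build one unit sequence for a spec; inner unit embedded centrally.
# Returns list(seq, inner_at = 0-based offset of the inner unit, inner)
build_repeat_unit <- function(spec) {
  if (is.null(spec$nesting)) {
    return(list(seq = rand_dna(spec$unit_len), inner_at = NA_integer_))
  }
  inner <- build_repeat_unit(spec$nesting)
  ilen <- nchar(inner$seq)
  if (spec$unit_len <= ilen)
    stop("nested repeat unit (", ilen, " bp) does not fit inside its ",
         "parent unit (", spec$unit_len, " bp)")
  pre <- (spec$unit_len - ilen) %/% 2L
  post <- spec$unit_len - ilen - pre
  list(seq = paste0(rand_dna(pre), inner$seq, rand_dna(post)),
       inner_at = pre, inner = inner)
}

# expand one spec into the array sequence plus per-copy annotation rows
# (level 1 = outermost).  `origin` is the 0-based offset of the array.
expand_repeat <- function(spec, origin, level = 1L, name = "R") {
  unit <- build_repeat_unit(spec)
  seqs <- character(0)
  ann <- data.frame(name = character(0), level = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  at <- origin
  add_ann <- function(nm, lv, s, e) {
    ann <<- rbind(ann, data.frame(name = nm, level = lv, start = s, end = e,
                                  stringsAsFactors = FALSE))
  }
  # annotate one placed unit (recursively annotating embedded inner units)
  annotate_unit <- function(u, spec0, at0, level0, name0) {
    add_ann(name0, level0, at0 + 1L, at0 + spec0$unit_len)
    if (!is.null(spec0$nesting) && !is.na(u$inner_at))
      annotate_unit(u$inner, spec0$nesting, at0 + u$inner_at, level0 + 1L,
                    paste0(name0, ".", level0 + 1L))
  }
  for (i in seq_len(spec$copies)) {
    useq <- mutate_seq(unit$seq, spec$divergence)
    annotate_unit(unit, spec, at, level, name)
    seqs <- c(seqs, useq)
    at <- at + nchar(useq)
    if (i < spec$copies) {
      sp <- rand_dna(spec$spacer)
      seqs <- c(seqs, sp)
      at <- at + nchar(sp)
    }
  }
  # standalone extra copies of inner repeats (beyond one per parent copy)
  placed <- spec$copies
  inner_spec <- spec$nesting
  inner_unit <- if (is.null(spec$nesting)) NULL else unit$inner
  lvl <- level + 1L
  while (!is.null(inner_spec)) {
    extra <- max(0L, inner_spec$copies - placed)
    for (i in seq_len(extra)) {
      sp <- rand_dna(inner_spec$spacer)
      seqs <- c(seqs, sp)
      at <- at + nchar(sp)
      useq <- mutate_seq(inner_unit$seq, inner_spec$divergence)
      annotate_unit(inner_unit, inner_spec, at, lvl, paste0(name, ".", lvl))
      seqs <- c(seqs, useq)
      at <- at + nchar(useq)
    }
    placed <- max(placed, inner_spec$copies)
    inner_unit <- if (is.null(inner_spec$nesting)) NULL else inner_unit$inner
    inner_spec <- inner_spec$nesting
    lvl <- lvl + 1L
  }
  list(seq = paste(seqs, collapse = ""), annotation = ann)
}

#' Generate a synthetic genome with planted tandem repeats
#'
#' A uniform-random background sequence with repeat arrays planted at
#' recorded coordinates.  Arrays are placed left to right at evenly spaced,
#' non-overlapping positions (deterministic given the seed), and every
#' repeat copy interval, at every nesting level, is reported in the truth
#' annotation.
#'
#' @param length genome length in bp.
#' @param repeats list of [repeat_spec()] objects (possibly empty).
#' @param seed integer seed.
#' @return List of class `synthetic_genome` with elements `seq` (one DNA
#'   string) and `annotation` (`data.frame`: `name`, `level`, `start`,
#'   `end`, 1-based inclusive).
#' @examples
#' g <- generate_genome(20000, list(repeat_spec(60, 3, 30)), seed = 1)
#' nchar(g$seq)
#' g$annotation
#' @export
generate_genome <- function(length, repeats = list(), seed = 1L) {
  if (inherits(repeats, "repeat_spec")) repeats <- list(repeats)
  set.seed(as.integer(seed))
  length <- as.integer(length)
  reg_lens <- vapply(repeats, repeat_region_len, 1L)
  if (sum(reg_lens) + 2L * (length(reg_lens) + 1L) > length)
    stop("repeat arrays (", sum(reg_lens), " bp) do not fit in a ",
         length, " bp genome")
  base <- rand_dna(length)
  ann <- data.frame(name = character(0), level = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  if (base::length(repeats)) {
    # evenly spaced origins keeping arrays clear of the termini
    n <- base::length(repeats)
    free <- length - sum(reg_lens)
    gap <- free %/% (n + 1L)
    at <- gap  # 0-based origin of the next array
    for (i in seq_len(n)) {
      ex <- expand_repeat(repeats[[i]], at, name = paste0("R", i))
      arr <- ex$seq
      substr(base, at + 1L, at + nchar(arr)) <- arr
      ann <- rbind(ann, ex$annotation)
      at <- at + nchar(arr) + gap
    }
  }
  structure(list(seq = base, annotation = ann), class = "synthetic_genome")
}

#' Simulate paired-end reads from a genome
#'
#' Fragment lengths are normal (clamped to at least `read_len`), fragment
#' start positions uniform over the template, and each fragment is sampled
#' from either strand with equal probability.  The first mate is the
#' fragment's 5' end read and the second mate the reverse complement of
#' its 3' end, so the two reads of a pair point toward each other and
#' their outer-5'-end span equals the insert size.  Substitution errors
#' are i.i.d. per base at `err_rate`; no indels are introduced.
#'
#' @param genome a DNA string, a `synthetic_genome`, or a named character
#'   vector (first element used).
#' @param coverage target nominal coverage (x).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size distribution in bp (the
#'   default 370 +/- 56 matches a standard 100 bp Illumina library).
#' @param err_rate per-base substitution probability.
#' @param seed integer seed; identical seeds give identical read sets.
#' @param tile_ends anchor one fragment at each genome terminus so the
#'   linear template has no terminal coverage ramp.
#' @return List of class `simulated_reads` with `pairs` (read-pair table
#'   usable by [build_kmer_index()]) and `placements` (truth: `id`,
#'   `mate`, `start` 1-based, `strand` of the read on the genome).
#' @examples
#' g <- generate_genome(10000, seed = 3)
#' sim <- simulate_pairs(g, coverage = 5, seed = 3)
#' nrow(sim$pairs)  # round(5 * 10000 / 200)
#' @export
simulate_pairs <- function(genome, coverage = 50, read_len = 100L,
                           insert_mean = 370, insert_sd = 56,
                           err_rate = 0, seed = 1L, tile_ends = TRUE) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$seq
  genome <- toupper(unname(genome)[1L])
  G <- nchar(genome)
  read_len <- as.integer(read_len)
  if (insert_mean <= read_len)
    stop("insert_mean must exceed the read length")
  if (G < insert_mean + 4 * insert_sd)
    stop("genome (", G, " bp) is shorter than the insert span")
  set.seed(as.integer(seed))
  np <- max(1L, as.integer(round(coverage * G / (2 * read_len))))
  fl <- pmax(read_len, as.integer(round(rnorm(np, insert_mean, insert_sd))))
  fl <- pmin(fl, G)
  st <- vapply(fl, function(f) sample.int(G - f + 1L, 1L), 1L)
  if (tile_ends && np >= 2L) {
    st[1L] <- 1L
    st[2L] <- G - fl[2L] + 1L
  }
  fwd <- runif(np) < 0.5
  frag <- substring(genome, st, st + fl - 1L)
  frag[!fwd] <- revcomp_dna(frag[!fwd])
  m1 <- substr(frag, 1L, read_len)
  m2 <- revcomp_dna(substr(frag, fl - read_len + 1L, fl))
  if (err_rate > 0) {
    m1 <- mutate_reads(m1, read_len, err_rate)
    m2 <- mutate_reads(m2, read_len, err_rate)
  }
  # truth placements: start/strand of each mate on the genome
  s1 <- ifelse(fwd, st, st + fl - read_len)
  s2 <- ifelse(fwd, st + fl - read_len, st)
  st1 <- ifelse(fwd, "+", "-")
  st2 <- ifelse(fwd, "-", "+")
  pairs <- data.frame(id = seq_len(np), seq1 = m1, seq2 = m2,
                      stringsAsFactors = FALSE)
  placements <- data.frame(
    id = rep(seq_len(np), 2L),
    mate = rep(c(1L, 2L), each = np),
    start = c(s1, s2),
    strand = c(st1, st2),
    insert = rep(fl, 2L),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, placements = placements,
                 genome_length = G, read_len = read_len,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 err_rate = err_rate),
            class = "simulated_reads")
}

mutate_reads <- function(v, L, rate) {
  ne <- rbinom(length(v), L, rate)
  ix <- which(ne > 0L)
  for (i in ix) {
    s <- strsplit(v[i], "")[[1]]
    pos <- sample.int(L, ne[i])
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    v[i] <- paste(s, collapse = "")
  }
  v
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat("simulated_reads:", nrow(x$pairs), "pairs of", x$read_len,
      "bp, insert", x$insert_mean, "+/-", x$insert_sd,
      "bp, err", x$err_rate, "\n")
  invisible(x)
}
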