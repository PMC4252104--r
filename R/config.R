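#' Assembly configuration
#'
#' Collects every tunable parameter of the assembler into a validated list.
#' The k-mer size doubles as the minimum overlap threshold `O_min`: a
#' single-end read must share at least `O_min` aligned bases with the
#' contig end before it may vote on the next base, and the k-mer hash
#' table is built for exactly that k so that an overlap of w >= k bases is
#' visible as w - k + 1 consecutive shared k-mers.
#'
#' @param k k-mer size in bp; equals the minimum overlap threshold `O_min`.
#' @param O_max largest single-end overlap threshold in bp.  The extension
#'   sweep tries `O_max` first and descends towards `O_min` only while no
#'   read overlap of the current size exists.
#' @param sample_fraction fraction of each read's k-mers that are indexed,
#'   taken half from each read end (positions closest to the termini).
#'   1.0 indexes every position.
#' @param linking_region length in bp of the contig ends used for
#'   scaffold-graph read alignment.
#' @param min_similarity minimum similarity between a read and the contig
#'   (or extracted path) over their overlap for the read to be assembled.
#' @param min_align_frac minimum fraction of a read's overlapped bases that
#'   must match for the read to be considered correctly aligned at all.
#' @param path_majority look-ahead per-column majority ratio below which a
#'   column counts as incorrect.
#' @param max_bad_positions look-ahead: fewer than this many low-majority
#'   columns means the branch is treated as sequencing error and extension
#'   continues.
#' @param min_path_overlap tandem-repeat resolution: candidate paths are
#'   merged when one path's suffix overlaps another's prefix by strictly
#'   more than this many bp.
#' @param min_contig_merge_overlap scaffolding: neighbouring contigs are
#'   merged when their end overlap exceeds this many bp and agrees with the
#'   estimated gap size.
#' @param insert_sd_mult width, in standard deviations, of the insert-size
#'   compatibility window used for paired support and spurious-path removal.
#' @param min_contig_len contigs shorter than this are not reported
#'   (approximately one read length).
#' @param low_freq_threshold seed k-mers whose index frequency does not
#'   strictly exceed this count are skipped as likely sequencing errors.
#' @param min_pairs_paired minimum supporting pairs for a decidable
#'   paired-end tally.
#' @param min_branch_support minimum reads behind the second-best base for
#'   an extension point to be treated as a branch; below it a lone
#'   dissenting vote is outvoted (majority extension) and a tie stops.
#' @param min_insert_n pairs that must be observed before the inferred
#'   insert-size model is trusted (enables paired-priority extension).
#' @param heur_ratio fallback navigator: continue when
#'   secOcc/maxOcc is below this ratio ...
#' @param heur_gap ... and gapLen does not exceed this many bp ...
#' @param heur_cov ... and covRatio does not exceed this value (elevated
#'   local read density flags a nearby repeat: extend more carefully).
#' @param navigation `"svm"` (trained model with the heuristic as fallback),
#'   `"heuristic"`, or `"majority"` (always extend with the majority base;
#'   used to produce training traces).
#' @param svm_margin decision values within `[-svm_margin, svm_margin]`
#'   (inclusive) are low confidence and handed to the look-ahead.
#' @param svm_C soft-margin penalty used when training the navigator.
#' @param use_lookahead logical; resolve low-confidence branches by path
#'   extraction instead of stopping.
#' @param max_contig_len safety cap on contig growth in bp.
#' @param trace_context bp of contig sequence stored with each traced
#'   branch decision; chosen to span what a paired read can resolve
#'   (about one insert span), so that truth labelling judges a branch at
#'   the same evidence scale the assembler works at.
#' @param seed integer seed for the run's random choices.
#'
#' @return An object of class `assembly_config` (a named list).
#' @examples
#' cfg <- assembly_config(k = 21, O_max = 50)
#' cfg$O_min
#' @export
assembly_config <- function(k = 25L,
                            O_max = 70L,
                            sample_fraction = 0.1,
                            linking_region = 2000L,
                            min_similarity = 0.95,
                            min_align_frac = 0.90,
                            path_majority = 0.9,
                            max_bad_positions = 3L,
                            min_path_overlap = 10L,
                            min_contig_merge_overlap = 3L,
                            insert_sd_mult = 2.0,
                            min_contig_len = 100L,
                            low_freq_threshold = 2L,
                            min_pairs_paired = 2L,
                            min_branch_support = 2L,
                            min_insert_n = 20L,
                            heur_ratio = 0.7,
                            heur_gap = 100L,
                            heur_cov = 1.5,
                            navigation = c("svm", "heuristic", "majority"),
                            svm_margin = 0.5,
                            svm_C = 1.0,
                            use_lookahead = TRUE,
                            max_contig_len = 10000000L,
                            trace_context = 500L,
                            seed = 1L) {
  navigation <- match.arg(navigation)
  cfg <- list(
    k = as.integer(k), O_min = as.integer(k), O_max = as.integer(O_max),
    sample_fraction = as.numeric(sample_fraction),
    linking_region = as.integer(linking_region),
    min_similarity = as.numeric(min_similarity),
    min_align_frac = as.numeric(min_align_frac),
    path_majority = as.numeric(path_majority),
    max_bad_positions = as.integer(max_bad_positions),
    min_path_overlap = as.integer(min_path_overlap),
    min_contig_merge_overlap = as.integer(min_contig_merge_overlap),
    insert_sd_mult = as.numeric(insert_sd_mult),
    min_contig_len = as.integer(min_contig_len),
    low_freq_threshold = as.integer(low_freq_threshold),
    min_pairs_paired = as.integer(min_pairs_paired),
    min_branch_support = as.integer(min_branch_support),
    min_insert_n = as.integer(min_insert_n),
    heur_ratio = as.numeric(heur_ratio),
    heur_gap = as.integer(heur_gap),
    heur_cov = as.numeric(heur_cov),
    navigation = navigation,
    svm_margin = as.numeric(svm_margin),
    svm_C = as.numeric(svm_C),
    use_lookahead = isTRUE(use_lookahead),
    max_contig_len = as.integer(max_contig_len),
    trace_context = as.integer(trace_context),
    seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "assembly_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$k >= 3L, cfg$k <= 31L,
    cfg$O_min == cfg$k,
    cfg$O_min <= cfg$O_max,
    cfg$sample_fraction > 0, cfg$sample_fraction <= 1,
    cfg$min_similarity > 0, cfg$min_similarity <= 1,
    cfg$min_align_frac > 0, cfg$min_align_frac <= 1,
    cfg$path_majority > 0, cfg$path_majority <= 1,
    cfg$max_bad_positions >= 1L,
    cfg$min_path_overlap >= 1L,
    cfg$min_contig_merge_overlap >= 1L,
    cfg$insert_sd_mult > 0,
    cfg$min_contig_len >= 1L,
    cfg$linking_region >= 1L,
    cfg$insert_sd_mult > 0)
  invisible(cfg)
}

#' @export
print.assembly_config <- function(x, ...) {
  cat("assembly_config: k = O_min =", x$k, " O_max =", x$O_max,
      " sampling =", x$sample_fraction, "\n")
  cat("  navigation:", x$navigation,
      if (x$use_lookahead) "+ lookahead" else "(no lookahead)", "\n")
  invisible(x)
}

# internal: configuration fields consumed by the C++ engine
cfg_for_engine <- function(cfg) {
  unclass(cfg)
}
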