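#' Run the capture-to-calls pipeline on a synthetic genome
#'
#' Convenience driver chaining the simulator and processing modules: capture
#' simulation, rPE library amplification, read generation, classification,
#' group splitting, coverage/pileup and variant calling.
#'
#' @param genome a \code{clpp_genome}.
#' @param panel a \code{clpp_panel} designed on \code{genome$reference}.
#' @param model a \code{clpp_capture_model}.
#' @param mode library mode, \code{"rpe"} or \code{"standard"}.
#' @param r1_len,r2_len read lengths.
#' @param depth read duplication multiplier.
#' @param error_rate per-base PCR substitution rate.
#' @param index sample index.
#' @param seed seed for amplification, read generation and tie-breaking.
#' @param mapq_min,baseq_min,evalue_cutoff processing filters.
#' @param min_depth genotyper depth threshold.
#' @return list with \code{captures, templates, reads, assignments, groups,
#'   coverage, calls}.
#' @export
run_capture_pipeline <- function(genome, panel, model = capture_model(),
                                 mode = c("rpe", "standard"),
                                 r1_len = 175L, r2_len = 150L, depth = 1L,
                                 error_rate = 0, index = "ACGTAC",
                                 seed = 1L, mapq_min = 30L, baseq_min = 20L,
                                 evalue_cutoff = 1e-6, min_depth = 20L) {
  mode <- match.arg(mode)
  captures <- simulate_capture(genome, panel, model)
  if (!nrow(captures)) stop("no molecules captured", call. = FALSE)
  templates <- amplify_rpe(captures, mode = mode, index = index,
                           error_rate = error_rate, seed = seed)
  reads <- generate_reads(templates, r1_len = r1_len, r2_len = r2_len,
                          depth = depth, seed = seed + 1L)
  refs <- panel$references
  assignments <- classify_reads(reads, refs, evalue_cutoff = evalue_cutoff,
                                seed = seed + 2L)
  groups <- split_groups(assignments, reads)
  coverage <- compute_coverage(assignments, reads, refs,
                               mapq_min = mapq_min, baseq_min = baseq_min)
  calls <- call_variants(coverage, refs, min_depth = min_depth)
  list(captures = captures, templates = templates, reads = reads,
       assignments = assignments, groups = groups, coverage = coverage,
       calls = calls)
}
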