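#' Pipeline thresholds and tunable parameters
#'
#' A single configuration object carrying every threshold the curation
#' pipeline uses. Defaults implement the published filtering rules:
#' log2 fold change under Dicer-1 depletion strictly below -0.5, hairpin
#' free energy strictly below -22 kcal/mol, more than 16 (i.e. >= 17)
#' mature/star paired bases, a 2-nt 3' overhang on each arm, conserved
#' assignment at >= 19 ungapped alignment columns with at most one
#' mismatch, co-mature arm ratio < 2, seed at mature positions 2-7.
#'
#' @param fc log2FC threshold (mature arm must be strictly below it).
#' @param energy free-energy threshold, kcal/mol (strictly below).
#' @param min_pairs minimum mature/star paired bases ("more than 16").
#' @param homogeneity minimum fraction of arm reads sharing the modal
#'   5' start (criterion 3; the published rule is qualitative, 0.66 is
#'   this package's default).
#' @param co_mature_ratio arm-count ratio below which both arms are
#'   called co-mature.
#' @param align_min_cols,align_max_mismatch conserved-assignment rule:
#'   ungapped alignment of at least this many columns with at most this
#'   many mismatches.
#' @param overhang,overhang_tol required 3' overhang per arm and the
#'   tolerated deviation (0 = exactly 2 nt).
#' @param loop_range sanity range for the terminal-loop length used by
#'   the hairpin-shape criterion.
#' @param arm_tolerance allowed 5'-end offset (nt) when assigning reads
#'   to an arm (isomiR wobble).
#' @param pseudocount RPM pseudocount for the log2FC ratio.
#' @param seed_positions 1-based inclusive positions of the seed.
#' @param neg_max_len,neg_min_cov negative-control region rule: maximal
#'   regions shorter than `neg_max_len` covered at least `neg_min_cov`
#'   fold in every control library.
#' @param cluster_max_gap maximum inter-locus gap (bp) chaining two
#'   precursors into one genomic cluster.
#' @param target_energy duplex free-energy threshold for target
#'   prediction, kcal/mol.
#' @param report_flank flanking nucleotides added to the precursor in
#'   per-miRNA reports.
#' @param read_length read-length window for report alignments.
#' @param precursor_flank flanking nucleotides compared when detecting
#'   assembly artifacts.
#' @return a named list with class `"mirThresholds"`.
#' @examples
#' th <- mirThresholds(energy = -20)
#' th$energy
#' @export
mirThresholds <- function(fc = -0.5,
                          energy = -22,
                          min_pairs = 17L,
                          homogeneity = 0.66,
                          co_mature_ratio = 2,
                          align_min_cols = 19L,
                          align_max_mismatch = 1L,
                          overhang = 2L,
                          overhang_tol = 0L,
                          loop_range = c(3L, 60L),
                          arm_tolerance = 2L,
                          pseudocount = 0.25,
                          seed_positions = c(2L, 7L),
                          neg_max_len = 500L,
                          neg_min_cov = 10L,
                          cluster_max_gap = 20000L,
                          target_energy = -12,
                          report_flank = 30L,
                          read_length = c(18L, 26L),
                          precursor_flank = 50L) {
  structure(list(
    fc = fc, energy = energy, min_pairs = as.integer(min_pairs),
    homogeneity = homogeneity, co_mature_ratio = co_mature_ratio,
    align_min_cols = as.integer(align_min_cols),
    align_max_mismatch = as.integer(align_max_mismatch),
    overhang = as.integer(overhang),
    overhang_tol = as.integer(overhang_tol),
    loop_range = as.integer(loop_range),
    arm_tolerance = as.integer(arm_tolerance),
    pseudocount = pseudocount,
    seed_positions = as.integer(seed_positions),
    neg_max_len = as.integer(neg_max_len),
    neg_min_cov = as.integer(neg_min_cov),
    cluster_max_gap = as.integer(cluster_max_gap),
    target_energy = target_energy,
    report_flank = as.integer(report_flank),
    read_length = as.integer(read_length),
    precursor_flank = as.integer(precursor_flank)
  ), class = "mirThresholds")
}
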