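#' Simulation configuration for the synthetic tiCLIP generator
#'
#' Collects every tunable of the generator with the study-condition
#' defaults: a DRB-release time course sampled at 0-60 minutes plus a
#' steady-state (DMSO) library, an elongation wave moving at 3.5 kb/min,
#' and the class-specific snoRNA 3'-extension offsets (9/25 nt for H/ACA,
#' variable up to 25 nt for CD-box).
#'
#' @param seed master seed; per-library sub-seeds are derived from it.
#' @param velocity_kb_per_min RNAPII elongation velocity (kb/min).
#' @param timepoints named numeric vector of minutes since DRB release;
#'   `Inf` denotes the steady-state (DMSO) library.
#' @param factor_model anchoring model of the simulated RBP: one of
#'   `"CAP_ANCHORED"` (exponential from the TSS, scale 50 nt),
#'   `"EXON3P_EJC"` (Gaussian centred 25 nt upstream of exon 3' ends,
#'   sd 8 nt), `"INTRON3P_LARIAT_SNORNA"` (uniform over the intron
#'   -100..-20 nt region, with lariat and snoRNA intermediates), or
#'   `"UNIFORM_NASCENT"` (uniform over transcribed sequence).
#' @param splice_halflife_min half-life (minutes) of each of the two
#'   splicing transesterification steps.
#' @param lariat_fraction fraction of excised introns still in lariat form.
#' @param circular_origin_fraction among lariat-derived cDNAs, the fraction
#'   reverse-transcribed from the circular portion (truncating on the BP
#'   with a mismatched terminal base); the rest are linear-origin
#'   (truncating 1 nt downstream of the BP).
#' @param haca_extension_offsets discrete 3'-extension offsets (nt) of
#'   H/ACA-box pre-snoRNAs.
#' @param cd_extension_max maximal CD-box extension; offsets are uniform on
#'   `1:cd_extension_max`.
#' @param rrna_fraction fraction of reads drawn from rRNA units.
#' @param pcr_dup_rate fraction of emitted reads that are PCR duplicates.
#' @param reads_per_library reads emitted per (timepoint, replicate)
#'   library, duplicates included.
#' @param umi_length,barcodes UMI length and per-replicate in-line barcodes.
#' @param fragment_length_range RNA fragment length range (nt); the minimum
#'   must be at least 20 nt, the practical mapping limit.
#' @param read_length sequenced read length (nt) of each mate.
#' @param pause_offset cap-proximal region (nt) transcribed during the DRB
#'   block (promoter-proximal pausing).
#' @param sno_intron_fraction fraction of eligible introns hosting a snoRNA
#'   in generated annotations.
#' @param sno_read_share among excised (debranched) snoRNA-host intron
#'   reads, the share that are pre-snoRNA 3'-extension intermediates
#'   rather than generic intron-3' contacts; pre-snoRNA intermediates
#'   dominate the downstream flank of snoRNA 3' ends.
#' @param n_rrna number of rRNA units in generated annotations.
#' @param bg_mismatch_rate background per-read probability of a random
#'   read1 mismatch (lariat circular-origin reads always carry a terminal
#'   mismatch).
#' @param tu_length_range TU length range (nt), sampled log-uniformly.
#' @param mono_exonic_fraction fraction of mono-exonic TUs.
#' @param max_exons maximal exon count per TU.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       velocity_kb_per_min = 3.5,
                       timepoints = c(t00 = 0, t05 = 5, t10 = 10, t15 = 15,
                                      t20 = 20, t30 = 30, t60 = 60,
                                      DMSO = Inf),
                       factor_model = c("CAP_ANCHORED", "EXON3P_EJC",
                                        "INTRON3P_LARIAT_SNORNA",
                                        "UNIFORM_NASCENT"),
                       splice_halflife_min = 3,
                       lariat_fraction = 0.3,
                       circular_origin_fraction = 0.5,
                       haca_extension_offsets = c(9L, 25L),
                       cd_extension_max = 25L,
                       rrna_fraction = 0.05,
                       pcr_dup_rate = 0.1,
                       reads_per_library = 10000L,
                       umi_length = 8L,
                       barcodes = c("AGTCAC", "CGATGT"),
                       fragment_length_range = c(25L, 80L),
                       read_length = 30L,
                       pause_offset = 300L,
                       sno_intron_fraction = 0.3,
                       sno_read_share = 0.75,
                       n_rrna = 4L,
                       bg_mismatch_rate = 0.001,
                       tu_length_range = c(1000L, 400000L),
                       mono_exonic_fraction = 0.2,
                       max_exons = 12L) {
  factor_model <- match.arg(factor_model)
  cfg <- list(seed = as.integer(seed),
              velocity_kb_per_min = velocity_kb_per_min,
              timepoints = timepoints, factor_model = factor_model,
              splice_halflife_min = splice_halflife_min,
              lariat_fraction = lariat_fraction,
              circular_origin_fraction = circular_origin_fraction,
              haca_extension_offsets = as.integer(haca_extension_offsets),
              cd_extension_max = as.integer(cd_extension_max),
              rrna_fraction = rrna_fraction, pcr_dup_rate = pcr_dup_rate,
              reads_per_library = as.integer(reads_per_library),
              umi_length = as.integer(umi_length), barcodes = barcodes,
              fragment_length_range = as.integer(fragment_length_range),
              read_length = as.integer(read_length),
              pause_offset = as.integer(pause_offset),
              sno_intron_fraction = sno_intron_fraction,
              sno_read_share = sno_read_share,
              n_rrna = as.integer(n_rrna),
              bg_mismatch_rate = bg_mismatch_rate,
              tu_length_range = as.integer(tu_length_range),
              mono_exonic_fraction = mono_exonic_fraction,
              max_exons = as.integer(max_exons))
  fr <- c("lariat_fraction", "circular_origin_fraction", "rrna_fraction",
          "pcr_dup_rate", "sno_intron_fraction", "sno_read_share",
          "mono_exonic_fraction", "bg_mismatch_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$velocity_kb_per_min <= 0) stop("velocity must be positive")
  if (cfg$splice_halflife_min <= 0) stop("splice half-life must be positive")
  if (cfg$fragment_length_range[1] < 20L) {
    stop("minimum fragment length is 20 nt (mapping limit)")
  }
  if (is.null(names(cfg$timepoints))) stop("timepoints must be named")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> model=", x$factor_model, ", v=", x$velocity_kb_per_min,
      " kb/min, ", length(x$timepoints), " timepoints x ",
      length(x$barcodes), " replicates, ", x$reads_per_library,
      " reads/library\n", sep = "")
  invisible(x)
}
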