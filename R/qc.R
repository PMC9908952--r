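#' Minimum co-migrating RNA length from an SDS-PAGE migration gap
#'
#' Approximately 70 nt of cross-linked RNA retards an RNP's gel migration
#' by 20 kDa, so the minimum RNA length needed to bridge a migration gap
#' of `gap_kda` is `ceiling(gap_kda / kda_per_step * nt_per_step)`
#' nucleotides of total RNA; subtracting the pre-ligated adapter gives
#' the cross-linked RNA proper. The ceiling (not rounding) reproduces the
#' 65 kDa worked example: 65/20 x 70 = 227.5 -> 228 nt total, 199 nt
#' after the 29 nt adapter.
#'
#' @param gap_kda migration gap in kDa (>= 0).
#' @param nt_per_step,kda_per_step the retardation rule (defaults 70 nt
#'   per 20 kDa).
#' @param adapter_nt adapter length ligated before electrophoresis
#'   (default 29).
#' @return list with `with_adapter_nt` (total RNA incl. adapter) and
#'   `rna_only_nt`.
#' @export
comigration_min_rna_length <- function(gap_kda, nt_per_step = 70L,
                                       kda_per_step = 20, adapter_nt = 29L) {
  if (gap_kda < 0) stop("migration gap must be non-negative")
  if (nt_per_step <= 0 || kda_per_step <= 0 || adapter_nt < 0) {
    stop("migration model parameters must be positive")
  }
  total <- as.integer(ceiling(gap_kda / kda_per_step * nt_per_step))
  list(with_adapter_nt = total,
       rna_only_nt = max(0L, total - as.integer(adapter_nt)))
}

#' Median insert size per library and pairwise differences
#'
#' Takes the absolute observed template length (TLEN) of each pair,
#' excluding zeros, and reports the per-library median (mean-of-middle
#' convention for even counts) together with all pairwise between-library
#' differences.
#'
#' @param libraries named list of `aligned_pairs`.
#' @return list with `median_nt` (named numeric, `NA` for empty
#'   libraries) and `differences` (data.frame of pairwise absolute
#'   differences).
#' @export
median_insert_size <- function(libraries) {
  med <- vapply(libraries, function(p) {
    t <- abs(p$tlen)
    t <- t[!is.na(t) & t > 0L]
    if (!length(t)) NA_real_ else stats::median(t)
  }, numeric(1))
  nm <- names(libraries)
  diffs <- NULL
  if (length(nm) > 1L) {
    cmb <- utils::combn(nm, 2L)
    diffs <- data.frame(library_a = cmb[1L, ], library_b = cmb[2L, ],
                        difference_nt = abs(med[cmb[1L, ]] - med[cmb[2L, ]]),
                        row.names = NULL)
  }
  list(median_nt = med, differences = diffs)
}
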