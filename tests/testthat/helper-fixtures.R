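# Shared in-code fixtures: a tiny hand-built annotation and planted pairs.

# Two TUs (one per strand) with known intron/BP/snoRNA geometry plus one
# rRNA unit. Plus-strand TU: exons [1000,1100) and [1600,1700), intron
# [1100,1600), BP at 1580 (dist 20), CD snoRNA [1400,1500).
# Minus-strand TU mirrors the same sense geometry on chrB.
tiny_annotation <- function() {
  tus <- data.frame(
    tu_id = c("tuP", "tuM"), chrom = c("chrA", "chrB"),
    start = c(1000L, 1000L), end = c(1700L, 1700L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    tu_id = c("tuP", "tuP", "tuM", "tuM"),
    rank = c(1L, 2L, 1L, 2L),
    start = c(1000L, 1600L, 1600L, 1000L),
    end = c(1100L, 1700L, 1700L, 1100L))
  introns <- data.frame(
    intron_id = c("tuP.i1", "tuM.i1"), tu_id = c("tuP", "tuM"),
    rank = c(1L, 1L), start = c(1100L, 1100L), end = c(1600L, 1600L),
    bp_pos = c(1580L, 1119L), bp_dist = c(20L, 20L),
    stringsAsFactors = FALSE)
  snornas <- data.frame(
    sno_id = c("snoP", "snoM"), intron_id = c("tuP.i1", "tuM.i1"),
    tu_id = c("tuP", "tuM"), sno_class = c("CD", "HACA"),
    start = c(1400L, 1200L), end = c(1500L, 1300L),
    stringsAsFactors = FALSE)
  rrna <- data.frame(unit_id = "rr1", chrom = "chrR", start = 100L,
                     end = 600L, strand = "+", stringsAsFactors = FALSE)
  ticlip_annotation(tus, exons, introns, snornas, rrna,
                    c(chrA = 3000L, chrB = 3000L, chrR = 1000L))
}

# One planted plus-strand pair with configurable coordinates.
plant_pair <- function(name = "p1", chrom = "chrA", strand = "+",
                       r1 = c(100L, 130L), r2 = c(180L, 210L),
                       umi = "AAAA", barcode = "ACGT", mm_pos = "",
                       mm_base = "", tlen = 110L) {
  aligned_pairs(name = name, umi = umi, barcode = barcode, chrom = chrom,
                strand = strand,
                r1_starts = as.character(r1[1]), r1_ends = as.character(r1[2]),
                r2_starts = as.character(r2[1]), r2_ends = as.character(r2[2]),
                mm_pos = mm_pos, mm_base = mm_base, tlen = tlen)
}

bind_pairs <- function(...) {
  as_aligned_pairs(do.call(rbind, lapply(list(...), as.data.frame)),
                   validate = FALSE)
}

# Small fast simulation shared by several tests.
quick_sim <- function(seed = 2L, model = "INTRON3P_LARIAT_SNORNA",
                      reads = 3000L, timepoints = c(DMSO = Inf),
                      barcodes = "AGTCAC", n_tu = 20L,
                      rrna_fraction = 0.03, ...) {
  cfg <- sim_config(seed = seed, factor_model = model,
                    reads_per_library = reads, timepoints = timepoints,
                    barcodes = barcodes, rrna_fraction = rrna_fraction, ...)
  ann <- make_annotation(n_tu, seed = seed, config = cfg)
  list(cfg = cfg, ann = ann, sim = simulate_timecourse(ann, cfg))
}

# Independent brute-force deconstruction used as the oracle for the
# vectorized site extractors: plain per-read loops over parsed blocks.
brute_force_sites <- function(pairs, mode = c("crosslink", "three_prime")) {
  mode <- match.arg(mode)
  out <- data.frame(chrom = character(0), strand = character(0),
                    pos = integer(0))
  for (i in seq_len(nrow(pairs))) {
    r1s <- as.integer(strsplit(pairs$r1_starts[i], ",")[[1]])
    r1e <- as.integer(strsplit(pairs$r1_ends[i], ",")[[1]])
    r2s <- as.integer(strsplit(pairs$r2_starts[i], ",")[[1]])
    r2e <- as.integer(strsplit(pairs$r2_ends[i], ",")[[1]])
    if (mode == "crosslink") {
      pos <- if (pairs$strand[i] == "+") r1s[1] - 1L else r1e[length(r1e)]
      if (pos < 0L) next
    } else {
      pos <- if (pairs$strand[i] == "+") r2e[length(r2e)] - 1L else r2s[1]
    }
    out <- rbind(out, data.frame(chrom = pairs$chrom[i],
                                 strand = pairs$strand[i], pos = pos))
  }
  site_track(out$chrom, out$strand, out$pos)
}
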