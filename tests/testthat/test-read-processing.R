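test_that("demultiplexing assigns, rejects and detects collisions", {
  tab <- c(ACGT = "s1", TTTT = "s2")
  p <- bind_pairs(plant_pair(name = "a", barcode = "ACGT"),
                  plant_pair(name = "b", barcode = "ACGA"),
                  plant_pair(name = "c", barcode = "TTTT"))
  out <- demultiplex(p, tab, max_mismatch = 0L)
  expect_equal(out$s1$name, "a")
  expect_equal(out$s2$name, "c")
  expect_equal(out$undetermined$name, "b")
  # with 1 mismatch allowed, ACGA resolves to s1
  out1 <- demultiplex(p, tab, max_mismatch = 1L)
  expect_setequal(out1$s1$name, c("a", "b"))
  expect_error(demultiplex(p, c(ACGT = "s1", ACGG = "s2"),
                           max_mismatch = 1L), "collision")
})

test_that("demultiplexed sample counts match simulator ground truth", {
  bcs <- c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")
  q <- quick_sim(seed = 21, reads = 500, n_tu = 8, barcodes = bcs)
  pooled <- as_aligned_pairs(
    do.call(rbind, lapply(q$sim$libraries, as.data.frame)),
    validate = FALSE)
  tab <- stats::setNames(paste0("rep", 1:4), bcs)
  out <- demultiplex(pooled, tab)
  gt <- q$sim$ground_truth
  for (i in 1:4) {
    expect_equal(nrow(out[[paste0("rep", i)]]),
                 sum(gt$barcode == bcs[i]))
  }
  expect_equal(nrow(out$undetermined), 0L)
})

test_that("deduplication keeps first record per UMI/coordinate key", {
  p <- bind_pairs(
    plant_pair(name = "a", umi = "AAAA"),
    plant_pair(name = "b", umi = "AAAA"),            # exact duplicate
    plant_pair(name = "c", umi = "AAAT"),            # different UMI
    plant_pair(name = "d", umi = "AAAA", r1 = c(101L, 131L),
               r2 = c(181L, 211L)))                  # different coordinate
  dd <- deduplicate(p)
  expect_equal(dd$name, c("a", "c", "d"))
  expect_equal(attr(dd, "n_duplicates"), 1L)
  expect_equal(as.data.frame(deduplicate(dd)), as.data.frame(dd),
               ignore_attr = TRUE)
  expect_equal(nrow(deduplicate(p[0, ])), 0L)
})

test_that("deduplication recovers the simulated non-duplicate count", {
  q <- quick_sim(seed = 30, reads = 4000, n_tu = 12, pcr_dup_rate = 0.3)
  p <- q$sim$libraries$DMSO.rep1
  gt <- q$sim$ground_truth
  dd <- deduplicate(p)
  expect_equal(nrow(dd), sum(!gt$is_pcr_duplicate))
  expect_equal(as.data.frame(deduplicate(dd)), as.data.frame(dd),
               ignore_attr = TRUE)
})

test_that("site extraction follows the published coordinate rules", {
  plus <- plant_pair(name = "p", strand = "+", r1 = c(100L, 130L),
                     r2 = c(180L, 210L))
  minus <- plant_pair(name = "m", chrom = "c1", strand = "-",
                      r1 = c(180L, 210L), r2 = c(100L, 130L))
  expect_equal(as.data.frame(crosslink_sites(plus))$pos, 99L)
  expect_equal(as.data.frame(crosslink_sites(minus))$pos, 210L)
  expect_equal(as.data.frame(three_prime_sites(plus))$pos, 209L)
  expect_equal(as.data.frame(three_prime_sites(minus))$pos, 100L)
  # read1 starting at 0 on + is dropped and counted, not clamped
  at0 <- plant_pair(name = "z", r1 = c(0L, 30L), r2 = c(60L, 90L))
  tr <- crosslink_sites(at0)
  expect_equal(nrow(tr), 0L)
  expect_equal(attr(tr, "n_dropped"), 1L)
})

test_that("whole-read coverage counts block positions and skips gaps", {
  one <- plant_pair(name = "w1", r1 = c(100L, 130L), r2 = c(150L, 180L))
  tr <- whole_read_coverage(one)
  expect_equal(nrow(tr), 30L)
  expect_true(all(tr$weight == 1))
  gapped <- aligned_pairs(name = "w2", umi = "AAAA", barcode = "B",
                          chrom = "c1", strand = "+",
                          r1_starts = "100,210", r1_ends = "110,220",
                          r2_starts = "230", r2_ends = "260", tlen = 50L)
  tr2 <- whole_read_coverage(gapped)
  expect_equal(nrow(tr2), 20L)
  expect_false(any(tr2$pos %in% 110:209))
})

test_that("vectorized deconstruction matches brute-force enumeration", {
  q <- quick_sim(seed = 14, reads = 1000, n_tu = 10,
                 timepoints = c(t20 = 20))
  p <- deduplicate(q$sim$libraries$t20.rep1)
  for (mode in c("crosslink", "three_prime")) {
    fast <- if (mode == "crosslink") crosslink_sites(p)
            else three_prime_sites(p)
    slow <- brute_force_sites(p, mode)
    expect_equal(as.data.frame(fast)[, c("chrom", "strand", "pos",
                                         "weight")],
                 as.data.frame(slow)[, c("chrom", "strand", "pos",
                                         "weight")])
  }
  # conservation and the strictly-upstream property
  tr <- crosslink_sites(p)
  expect_equal(track_total(tr) + attr(tr, "n_dropped"), nrow(p))
  r1_first <- as.integer(sub(",.*", "", p$r1_starts))
  r1_last <- as.integer(sub(".*,", "", p$r1_ends))
  site <- ifelse(p$strand == "+", r1_first - 1L, r1_last)
  expect_false(any(site >= r1_first & site < r1_last))
})

test_that("splice-status classification applies the boundary rules", {
  exons <- data.frame(exon_id = "e1", chrom = "c1", strand = "+",
                      start = 90L, end = 100L,
                      next_start = 200L, next_end = 210L)
  spliced <- aligned_pairs(name = "s", umi = "AAAA", barcode = "B",
                           chrom = "c1", strand = "+",
                           r1_starts = "90,200", r1_ends = "100,210",
                           r2_starts = "200", r2_ends = "210", tlen = 20L)
  contig <- plant_pair(name = "n", chrom = "c1", r1 = c(90L, 105L),
                       r2 = c(95L, 110L))
  ends_at <- plant_pair(name = "x", chrom = "c1", r1 = c(90L, 100L),
                        r2 = c(95L, 100L))
  res <- classify_splice_status(bind_pairs(spliced, contig, ends_at), exons)
  expect_equal(res$spliced, 1L)
  expect_equal(res$non_spliced, 1L)
  # minus-strand mirror: exon [200,210), downstream exon [90,100)
  exons_m <- data.frame(exon_id = "em", chrom = "c1", strand = "-",
                        start = 200L, end = 210L,
                        next_start = 90L, next_end = 100L)
  spliced_m <- aligned_pairs(name = "sm", umi = "AAAA", barcode = "B",
                             chrom = "c1", strand = "-",
                             r1_starts = "90,200", r1_ends = "100,210",
                             r2_starts = "90", r2_ends = "100", tlen = 20L)
  res_m <- classify_splice_status(spliced_m, exons_m)
  expect_equal(res_m$spliced, 1L)
  # exon without downstream partner is skipped with a warning
  expect_warning(
    classify_splice_status(contig,
                           data.frame(exon_id = "e2", chrom = "c1",
                                      strand = "+", start = 90L, end = 100L,
                                      next_start = NA, next_end = NA)),
    "skipped")
})
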