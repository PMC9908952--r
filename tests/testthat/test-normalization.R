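test_that("rRNA factor is count/divisor, strand-aware, and guards zero", {
  ann <- tiny_annotation()
  # 5 sense reads inside the rRNA unit, 2 antisense, 1 genic
  sense <- lapply(1:5, function(i) {
    plant_pair(name = paste0("r", i), chrom = "chrR",
               r1 = c(150L + i, 180L + i), r2 = c(200L, 230L))
  })
  anti <- lapply(1:2, function(i) {
    plant_pair(name = paste0("x", i), chrom = "chrR", strand = "-",
               r1 = c(200L, 230L), r2 = c(150L, 180L))
  })
  genic <- plant_pair(name = "g", chrom = "chrA",
                      r1 = c(1010L, 1040L), r2 = c(1050L, 1080L))
  p <- do.call(bind_pairs, c(sense, anti, list(genic)))
  nf <- rrna_factor(p, ann$rrna, divisor = 30000L)
  expect_equal(nf$rrna_read_count, 5L)
  expect_equal(nf$factor, 5 / 30000)
  expect_error(rrna_factor(genic, ann$rrna), "cannot be normalized")
})

test_that("a library with 30,000 rRNA reads has factor exactly 1", {
  n <- 30000L
  df <- data.frame(
    name = sprintf("r%05d", seq_len(n)), umi = "AAAA", barcode = "B",
    chrom = "chrR", strand = "+",
    r1_starts = as.character(100L + seq_len(n) %% 400L),
    r1_ends = as.character(130L + seq_len(n) %% 400L),
    r2_starts = "500", r2_ends = "530", mm_pos = "", mm_base = "",
    tlen = 60L, stringsAsFactors = FALSE)
  p <- as_aligned_pairs(df, validate = FALSE)
  nf <- rrna_factor(p, tiny_annotation()$rrna)
  expect_identical(nf$factor, 1)
  # linearity: doubling the count doubles the factor
  nf2 <- rrna_factor(p, tiny_annotation()$rrna, divisor = 15000L)
  expect_identical(nf2$factor, 2)
})

test_that("track scaling divides by the factor and is invertible", {
  tr <- site_track(c("c1", "c1"), c("+", "-"), c(5L, 9L), c(10, 4))
  nf <- structure(list(rrna_read_count = 60000L, divisor = 30000L,
                       factor = 2), class = "normalization_factor")
  sc <- scale_track(tr, nf)
  expect_equal(sc$weight, c(5, 2))
  expect_equal(track_total(sc), track_total(tr) / 2)
  expect_equal(scale_track(sc, 1 / nf$factor)$weight, tr$weight)
  expect_equal(scale_track(tr, 1)$weight, tr$weight)
  expect_equal(scale_track(tr, nf, direction = "multiply")$weight,
               tr$weight * 2)
  expect_error(scale_track(tr, 0), "positive")
})

test_that("expression normalization divides and skips bad TUs", {
  v <- c(tu1 = 8, tu2 = 6, tu3 = 4)
  expect_equal(expression_normalize(v, c(tu1 = 2, tu2 = 1, tu3 = 1)),
               c(tu1 = 4, tu2 = 6, tu3 = 4))
  expect_warning(out <- expression_normalize(v, c(tu1 = 2, tu2 = 1)),
                 "missing")
  expect_equal(names(out), c("tu1", "tu2"))
  expect_warning(out2 <- expression_normalize(v, c(tu1 = 2, tu2 = 0,
                                                   tu3 = 1)),
                 "non-positive")
  expect_equal(names(out2), c("tu1", "tu3"))
})

test_that("region density is reads/kb and invariant to subdivision", {
  tr <- site_track(rep("c1", 100), "+", seq(0L, 1980L, by = 20L), 1)
  reg <- data.frame(group = "exon", chrom = "c1", strand = "+",
                    start = 0L, end = 2000L)
  expect_equal(unname(region_density(tr, reg)), 50)
  split2 <- data.frame(group = "exon", chrom = "c1", strand = "+",
                       start = c(0L, 700L), end = c(700L, 2000L))
  expect_equal(region_density(tr, split2), region_density(tr, reg))
  expect_equal(unname(region_density(site_track(), reg)), 0)
  expect_error(region_density(tr, reg[0, ]), "non-empty")
})
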