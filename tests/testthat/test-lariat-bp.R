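test_that("BP window matrix anchors on the branch adenosine", {
  ann <- tiny_annotation()
  # site exactly on the plus-strand BP (1580) -> offset 0 in row 20
  tr <- site_track("chrA", "+", 1580L)
  m <- bp_window_matrix(tr, ann)
  expect_equal(rownames(m), as.character(18:38))
  expect_equal(unname(m["20", "0"]), 0.5)   # 2 BPs at distance 20, 1 hit
  expect_equal(sum(m), 0.5)
  # zero-BP distances are flagged
  expect_true(all(attr(m, "n_bp")[as.character(c(18, 38))] == 0L))
})

test_that("3'CLIP at intron ends tracks the BP distance diagonal", {
  q <- quick_sim(seed = 31, reads = 12000, n_tu = 25,
                 lariat_fraction = 0.6, sno_intron_fraction = 0)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  m <- bp_window_matrix(three_prime_sites(dd), q$ann)
  n_bp <- attr(m, "n_bp")
  hits <- 0L; total <- 0L
  for (d in 18:38) {
    if (n_bp[as.character(d)] < 2L) next
    total <- total + 1L
    peak <- as.integer(colnames(m)[which.max(m[as.character(d), ])])
    # lariat/intron-3' termini pile on the last intron nucleotide,
    # offset d - 1 from the branch adenosine
    if (peak == d - 1L) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.8)
})

test_that("truncation signatures separate circular and linear origins", {
  base <- list(seed = 33, reads = 8000, n_tu = 20,
               sno_intron_fraction = 0, lariat_fraction = 0.7)
  q_c <- do.call(quick_sim, c(base, circular_origin_fraction = 1))
  dd <- deduplicate(q_c$sim$libraries$DMSO.rep1)
  ts <- truncation_signature(five_prime_sites(dd), q_c$ann, "bp")
  expect_equal(ts$peak_offsets, 0L)
  q_l <- do.call(quick_sim, c(base, circular_origin_fraction = 0))
  dd_l <- deduplicate(q_l$sim$libraries$DMSO.rep1)
  ts_l <- truncation_signature(five_prime_sites(dd_l), q_l$ann, "bp")
  expect_equal(ts_l$peak_offsets, 1L)
  # no lariats -> no peaks at the BP or the intron 5' end
  q_0 <- do.call(quick_sim, c(base[1:3], lariat_fraction = 0))
  dd_0 <- deduplicate(q_0$sim$libraries$DMSO.rep1)
  for (anc in c("bp", "intron_5p")) {
    ts_0 <- truncation_signature(five_prime_sites(dd_0), q_0$ann, anc)
    expect_false(any(ts_0$peak_offsets %in% 0:1))
  }
})

test_that("circular-origin fraction is recovered from truncation mass", {
  q <- quick_sim(seed = 35, reads = 10000, n_tu = 20,
                 sno_intron_fraction = 0, lariat_fraction = 0.7,
                 circular_origin_fraction = 0.5)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  ts <- truncation_signature(five_prime_sites(dd), q$ann, "bp")
  m0 <- ts$counts[["0"]]
  m1 <- ts$counts[["1"]]
  phi_hat <- m0 / (m0 + m1)
  n <- m0 + m1
  expect_lt(abs(phi_hat - 0.5), 4 * sqrt(0.25 / n))
  expect_setequal(ts$peak_offsets, c(0L, 1L))
})

test_that("first-base mismatch rates flag circular-origin reads", {
  q <- quick_sim(seed = 37, reads = 8000, n_tu = 20,
                 sno_intron_fraction = 0, lariat_fraction = 0.7,
                 circular_origin_fraction = 0.5, bg_mismatch_rate = 0.001)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  mp <- mismatch_profile(dd, q$ann, "bp")
  expect_gt(mp$rate[["0"]], 0.9)
  expect_lt(mp$rate[["1"]], 0.05)
  expect_true(all(mp$mismatch_count <= mp$read_5p_count))
  # offsets with no read 5' ends report NA, not 0
  empty <- mismatch_profile(dd[0, ], q$ann, "bp")
  expect_true(all(is.na(empty$rate)))
})

test_that("window extractions flip exactly under genome mirroring", {
  ann <- tiny_annotation()
  set.seed(99)
  pos <- 1530L + sample.int(90L, 40, replace = TRUE)
  tr <- site_track("chrA", "+", pos, 1)
  m <- bp_window_matrix(tr, ann)
  L <- 3000L
  ann_m <- ann
  for (tab in c("tus", "exons", "introns", "snornas", "rrna")) {
    s <- ann_m[[tab]]$start
    ann_m[[tab]]$start <- L - ann_m[[tab]]$end
    ann_m[[tab]]$end <- L - s
  }
  ann_m$tus$strand <- ifelse(ann$tus$strand == "+", "-", "+")
  ann_m$rrna$strand <- ifelse(ann$rrna$strand == "+", "-", "+")
  ann_m$introns$bp_pos <- L - 1L - ann$introns$bp_pos
  tr_m <- site_track("chrA", "-", L - 1L - pos, 1)
  m_m <- bp_window_matrix(tr_m, ann_m)
  expect_equal(m_m, m, ignore_attr = TRUE)
})
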