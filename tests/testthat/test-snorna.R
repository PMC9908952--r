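test_that("snoRNA windows anchor at the 3' end and the host 3'SS", {
  ann <- tiny_annotation()
  # tuP CD snoRNA [1400,1500): last nt 1499, site at +9 -> 1508
  tr <- site_track("chrA", "+", 1508L)
  prof <- snorna_window_coverage(tr, ann, anchor = "sno_3p_end")
  expect_equal(names(which(prof$CD > 0)), "9")
  expect_equal(sum(prof$CD), 1)    # normalized per snoRNA count (1 CD)
  # host_3ss anchor: site at the intron's last nt (1599) -> offset 0
  tr2 <- site_track("chrA", "+", 1599L)
  prof2 <- snorna_window_coverage(tr2, ann, anchor = "host_3ss")
  expect_equal(names(which(prof2$CD > 0)), "0")
  # minus-strand H/ACA snoRNA [1200,1300): 3' end last nt at 1200,
  # +9 extension at genomic 1191
  tr3 <- site_track("chrB", "-", 1191L)
  prof3 <- snorna_window_coverage(tr3, ann, anchor = "sno_3p_end")
  expect_equal(names(which(prof3$HACA > 0)), "9")
})

test_that("class stratification partitions the unstratified profile", {
  q <- quick_sim(seed = 41, reads = 6000, n_tu = 20,
                 sno_intron_fraction = 0.5)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  t3 <- three_prime_sites(dd)
  raw <- snorna_window_coverage(t3, q$ann, normalize = FALSE)
  both <- q$ann
  both$snornas$sno_class <- "CD"   # collapse classes -> unstratified sum
  un <- snorna_window_coverage(t3, both, normalize = FALSE)
  expect_equal(raw$CD + raw$HACA, un$CD)
})

test_that("planted extension offsets are recovered per class", {
  q <- quick_sim(seed = 43, reads = 15000, n_tu = 30,
                 lariat_fraction = 0.2, sno_intron_fraction = 0.5,
                 rrna_fraction = 0.02)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  gt <- q$sim$ground_truth
  expect_gt(sum(!is.na(gt$ext_offset)), 1000L)  # >=500 reads/class regime
  prof <- snorna_window_coverage(three_prime_sites(dd), q$ann)
  pk_h <- extension_peaks(prof$HACA)
  expect_setequal(pk_h$peak_offsets, c(9L, 25L))
  expect_equal(pk_h$max_extension, 25L)
  pk_c <- extension_peaks(prof$CD)
  expect_length(pk_c$peak_offsets, 0L)
  expect_equal(pk_c$max_extension, 25L)
  # 3'CLIP termini match snoRNA 3' end + planted offset exactly
  sn <- q$ann$snornas
  tus <- q$ann$tus
  sel <- which(!is.na(gt$ext_offset))
  ms <- match(gt$unit_id[sel], tus$tu_id)
  host <- sn[match(paste0(gt$unit_id[sel]), sn$tu_id), , drop = FALSE]
  ok <- vapply(seq_along(sel), function(i) {
    hosts <- sn[sn$tu_id == gt$unit_id[sel][i], , drop = FALSE]
    plus <- tus$strand[ms[i]] == "+"
    expected <- if (plus) hosts$end - 1L + gt$ext_offset[sel][i]
                else hosts$start - gt$ext_offset[sel][i]
    gt$frag3p_pos[sel][i] %in% expected
  }, logical(1))
  expect_true(all(ok))
})

test_that("flat or empty profiles yield no peaks and zero extension", {
  empty <- stats::setNames(rep(0, 101), -50:50)
  pk <- extension_peaks(empty)
  expect_length(pk$peak_offsets, 0L)
  expect_equal(pk$max_extension, 0L)
})

test_that("top-N heatmaps rank by cumulative signal with stable ties", {
  ann <- tiny_annotation()
  # give the CD snoRNA (snoP) more downstream signal than snoM
  tr <- site_track(c(rep("chrA", 3), "chrB"), c("+", "+", "+", "-"),
                   c(1505L, 1506L, 1507L, 1195L), 1)
  m <- top_n_heatmap(tr, ann, n = 2L)
  expect_equal(rownames(m), c("snoP", "snoM"))
  expect_equal(unname(attr(m, "scores")), c(3, 1))
  # exact ties broken by id, lexicographically
  tr_tie <- site_track(c("chrA", "chrB"), c("+", "-"), c(1505L, 1195L), 1)
  m_tie <- top_n_heatmap(tr_tie, ann, n = 2L)
  expect_equal(rownames(m_tie), c("snoM", "snoP"))
  # n larger than the snoRNA count returns all rows
  expect_equal(nrow(top_n_heatmap(tr, ann, n = 50L)), 2L)
})

test_that("upstream flank binding does not grow across the time course", {
  q <- quick_sim(seed = 47, reads = 8000, n_tu = 20,
                 timepoints = c(t10 = 10, t60 = 60, DMSO = Inf),
                 sno_intron_fraction = 0.5, lariat_fraction = 0.2)
  up_mass <- down_mass <- numeric(0)
  for (l in names(q$sim$libraries)) {
    dd <- deduplicate(q$sim$libraries[[l]])
    pr <- snorna_window_coverage(three_prime_sites(dd), q$ann,
                                 normalize = FALSE)
    tot <- sum(pr$CD + pr$HACA)
    up_mass <- c(up_mass, sum((pr$CD + pr$HACA)[as.character(-50:-30)]))
    down_mass <- c(down_mass, sum((pr$CD + pr$HACA)[as.character(1:35)]))
  }
  # downstream (extension) signal accumulates with time
  expect_gt(down_mass[3], down_mass[1])
  # the upstream flank does not show a comparable increase
  expect_lt(up_mass[3] - up_mass[1], down_mass[3] - down_mass[1])
})
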