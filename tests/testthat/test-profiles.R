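test_that("spatiotemporal profiles stratify, bin, and max-normalize", {
  # one 25-kb TU -> group [20,30)kb with 25 bins
  tus <- data.frame(tu_id = "t1", chrom = "c1", start = 0L, end = 25000L,
                    strand = "+", stringsAsFactors = FALSE)
  ann <- ticlip_annotation(
    tus, data.frame(tu_id = "t1", rank = 1L, start = 0L, end = 25000L),
    data.frame(intron_id = character(0), tu_id = character(0),
               rank = integer(0), start = integer(0), end = integer(0),
               bp_pos = integer(0), bp_dist = integer(0)),
    data.frame(sno_id = character(0), intron_id = character(0),
               tu_id = character(0), sno_class = character(0),
               start = integer(0), end = integer(0)),
    data.frame(unit_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               strand = character(0)),
    c(c1 = 30000L))
  # bin means 2, 4, 8 in bins 1..3 -> normalized 0.25, 0.5, 1
  tr <- site_track(rep("c1", 14), "+",
                   c(1:2, 1001:1004, 2001:2008), 1)
  sp <- spatiotemporal_matrix(tr, ann)
  expect_named(sp$groups, "[20,30)kb")
  g <- sp$groups[[1]]
  expect_length(g$profile, 25L)
  expect_equal(g$profile[1:3], c(0.25, 0.5, 1))
  expect_equal(max(g$profile), 1)
  expect_true(all(g$profile >= 0 & g$profile <= 1))
})

test_that("cap-anchored signal at t0 concentrates in the first bin", {
  q <- quick_sim(seed = 17, model = "CAP_ANCHORED", reads = 3000,
                 n_tu = 15, timepoints = c(t00 = 0), rrna_fraction = 0)
  tr <- crosslink_sites(deduplicate(q$sim$libraries$t00.rep1))
  sp <- spatiotemporal_matrix(tr, q$ann)
  for (g in sp$groups) {
    expect_gt(g$raw_mean[1] / sum(g$raw_mean), 0.9)
  }
})

test_that("wave velocity is the OLS slope of detected fronts", {
  fake_profiles <- function(front_bins, nbins = 80) {
    lapply(front_bins, function(fb) {
      pr <- c(rep(1, fb), rep(0, nbins - fb))
      structure(list(groups = list(">=300kb" = list(
        profile = pr, raw_mean = pr, n_tu = 5L))),
        class = "spatiotemporal_profiles")
    })
  }
  mins <- c(t05 = 5, t10 = 10, t15 = 15, t20 = 20)
  profs <- fake_profiles(c(17.5, 35, 52.5, 70) %/% 1)
  names(profs) <- names(mins)
  w <- estimate_wave_velocity(profs, mins, smooth_bins = 1L)
  expect_equal(w$velocity_kb_per_min, 3.5, tolerance = 0.01)
  # stationary profiles -> slope 0
  st <- fake_profiles(rep(10, 4)); names(st) <- names(mins)
  w0 <- estimate_wave_velocity(st, mins, smooth_bins = 1L)
  expect_equal(w0$velocity_kb_per_min, 0)
  expect_error(estimate_wave_velocity(profs[1:2], mins[1:2]),
               "at least 3")
})

test_that("exon-anchored windows are strand-oriented", {
  ann <- tiny_annotation()
  # site 25 nt upstream of tuP exon1 3' end (last nt 1099) -> offset -25
  tr_p <- site_track("chrA", "+", 1074L)
  ex_p <- ann$exons[ann$exons$tu_id == "tuP" & ann$exons$rank == 1L, ]
  pr_p <- exon_anchored_profile(tr_p, ex_p, ann, end = "3p")
  expect_equal(names(which(pr_p > 0)), "-25")
  # mirrored site for tuM exon1 (last nt at genomic 1600) -> offset -25
  tr_m <- site_track("chrB", "-", 1625L)
  ex_m <- ann$exons[ann$exons$tu_id == "tuM" & ann$exons$rank == 1L, ]
  pr_m <- exon_anchored_profile(tr_m, ex_m, ann, end = "3p")
  expect_equal(names(which(pr_m > 0)), "-25")
  expect_error(exon_anchored_profile(tr_p, ex_p, ann, window = 200L),
               "odd")
})

test_that("EJC-like simulations peak ~25 nt upstream of exon 3' ends", {
  q <- quick_sim(seed = 19, model = "EXON3P_EJC", reads = 6000,
                 n_tu = 25, rrna_fraction = 0)
  dd <- deduplicate(q$sim$libraries$DMSO.rep1)
  n_ex <- stats::ave(q$ann$exons$rank, q$ann$exons$tu_id, FUN = max)
  internal <- q$ann$exons[q$ann$exons$rank > 1 & q$ann$exons$rank < n_ex, ]
  pr <- exon_anchored_profile(crosslink_sites(dd), internal, q$ann, "3p")
  mode_off <- as.integer(names(which.max(pr)))
  expect_lte(abs(mode_off - (-25L)), 3L)
})

test_that("3'CLIP signal at first-exon ends rises then falls", {
  q <- quick_sim(seed = 23, model = "EXON3P_EJC", reads = 5000, n_tu = 20,
                 timepoints = c(t00 = 0, t05 = 5, t10 = 10, t60 = 60),
                 rrna_fraction = 0)
  at0 <- vapply(names(q$sim$libraries), function(l) {
    h <- three_prime_end_histogram(
      three_prime_sites(deduplicate(q$sim$libraries[[l]])), q$ann)
    h$at_zero
  }, numeric(1))
  expect_gt(max(at0[c("t05.rep1", "t10.rep1")]), at0["t00.rep1"])
  expect_gt(max(at0[c("t05.rep1", "t10.rep1")]), at0["t60.rep1"])
  # empty track -> all zeros
  h0 <- three_prime_end_histogram(site_track(), q$ann)
  expect_true(all(h0$profile == 0))
})

test_that("exon-rank densities follow region_density semantics", {
  ann <- tiny_annotation()
  expect_equal(unname(exon_rank_density(site_track(), ann)),
               rep(0, 4))
  # uniform coverage of tuP exons -> equal first1/last1 densities
  tr <- site_track("chrA", "+", c(1000:1099, 1600:1699), 1)
  d <- exon_rank_density(tr, ann)
  expect_equal(unname(d["first1"]), unname(d["last1"]))
})

test_that("mature profiles are filtered, binned and unit-sum", {
  tus <- data.frame(tu_id = c("big", "small"), chrom = "c1",
                    start = c(0L, 5000L), end = c(1000L, 5150L),
                    strand = "+", stringsAsFactors = FALSE)
  ann <- ticlip_annotation(
    tus,
    data.frame(tu_id = c("big", "small"), rank = 1L,
               start = c(0L, 5000L), end = c(1000L, 5150L)),
    data.frame(intron_id = character(0), tu_id = character(0),
               rank = integer(0), start = integer(0), end = integer(0),
               bp_pos = integer(0), bp_dist = integer(0)),
    data.frame(sno_id = character(0), intron_id = character(0),
               tu_id = character(0), sno_class = character(0),
               start = integer(0), end = integer(0)),
    data.frame(unit_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               strand = character(0)),
    c(c1 = 6000L))
  # 25 sites all in the first 10 nt of a 1000-nt TU -> bin 1 = 1
  tr <- site_track(rep("c1", 25), "+", rep(0:9, length.out = 25), 1)
  mp <- mature_profile(tr, ann, "big")
  expect_false(mp$excluded)
  expect_equal(mp$bin_values[1], 1)
  expect_equal(sum(mp$bin_values), 1)
  # 150-nt TU excluded by length regardless of reads
  tr_s <- site_track(rep("c1", 30), "+", 5000L + (0:29), 1)
  expect_equal(mature_profile(tr_s, ann, "small")$reason, "length")
  # exactly 20 reads excluded (strict filter)
  tr20 <- site_track(rep("c1", 20), "+", 0:19, 1)
  expect_equal(mature_profile(tr20, ann, "big")$reason, "reads")
  tr21 <- site_track(rep("c1", 21), "+", 0:20, 1)
  expect_false(mature_profile(tr21, ann, "big")$excluded)
})

test_that("mature profiles mirror exactly under strand reversal", {
  q <- quick_sim(seed = 27, model = "UNIFORM_NASCENT", reads = 4000,
                 n_tu = 6, rrna_fraction = 0)
  tr <- crosslink_sites(deduplicate(q$sim$libraries$DMSO.rep1))
  ann <- q$ann
  L <- max(ann$chrom_lengths) + 10L
  flip_str <- function(s) ifelse(s == "+", "-", "+")
  mirror_tab <- function(df) {
    s <- df$start
    df$start <- L - df$end
    df$end <- L - s
    df
  }
  ann_m <- ann
  ann_m$tus <- mirror_tab(ann$tus)
  ann_m$tus$strand <- flip_str(ann$tus$strand)
  ann_m$exons <- mirror_tab(ann$exons)
  tr_m <- site_track(tr$chrom, flip_str(tr$strand), L - 1L - tr$pos,
                     tr$weight)
  for (id in ann$tus$tu_id) {
    a <- mature_profile(tr, ann, id)
    b <- mature_profile(tr_m, ann_m, id)
    expect_equal(a$excluded, b$excluded)
    if (!a$excluded) expect_equal(b$bin_values, a$bin_values)
  }
})

test_that("replicate-intersected k-means recovers planted archetypes", {
  sim <- simulate_profile_archetypes(seed = 11)
  cl <- kmeans_profile_groups(sim$profiles, k = 3, seed = 11)
  expect_length(cl$groups, 2L)
  g1 <- cl$groups$group1
  g2 <- cl$groups$group2
  expect_length(intersect(g1, g2), 0L)
  planted <- names(sim$truth)[sim$truth != "noise"]
  recovered <- sum(startsWith(g1, "tuA")) + sum(startsWith(g2, "tuB"))
  expect_gte(recovered / length(planted), 0.95)
  # group1 is the 5'-enriched archetype by the ordering convention
  expect_gt(mean(startsWith(g1, "tuA")), 0.95)
  # determinism and the identical-replicates identity
  cl2 <- kmeans_profile_groups(sim$profiles, k = 3, seed = 11)
  expect_identical(cl$groups, cl2$groups)
  same <- kmeans_profile_groups(list(sim$profiles[[1]], sim$profiles[[1]]),
                                k = 3, seed = 11)
  expect_equal(sum(is.na(same$assignments$final)), 0L)
  expect_error(kmeans_profile_groups(sim$profiles, k = 1000, seed = 1),
               "exceeds")
})

test_that("junction density profiles bin mature junction positions", {
  tus <- data.frame(tu_id = "j1", chrom = "c1", start = 0L, end = 2000L,
                    strand = "+", stringsAsFactors = FALSE)
  ann <- ticlip_annotation(
    tus,
    data.frame(tu_id = "j1", rank = 1:2, start = c(0L, 1900L),
               end = c(100L, 2000L)),
    data.frame(intron_id = "j1.i1", tu_id = "j1", rank = 1L,
               start = 100L, end = 1900L, bp_pos = 1880L, bp_dist = 20L),
    data.frame(sno_id = character(0), intron_id = character(0),
               tu_id = character(0), sno_class = character(0),
               start = integer(0), end = integer(0)),
    data.frame(unit_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               strand = character(0)),
    c(c1 = 3000L))
  # mature length 200, junction after 100 nt -> 50% -> bin 51
  v <- junction_density_profile(ann, "j1")
  expect_equal(sum(v), 1)
  expect_equal(which(v > 0), 51L)
})
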