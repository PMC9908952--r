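# Shared strand-oriented window extraction: offsets are in transcript
# orientation with the anchor at 0 (negative = upstream of the anchor).

.window_matrix <- function(track, chrom, pos, strand, lo, hi) {
  lookup <- .track_lookup(track)
  offs <- lo:hi
  sgn <- .strand_sign(strand)
  out <- matrix(0, nrow = length(pos), ncol = length(offs),
                dimnames = list(NULL, offs))
  for (k in seq_along(offs)) {
    out[, k] <- lookup(chrom, strand, pos + sgn * offs[k])
  }
  out
}

.window_aggregate <- function(track, chrom, pos, strand, lo, hi) {
  colSums(.window_matrix(track, chrom, pos, strand, lo, hi))
}

.length_group <- function(len) {
  ifelse(len >= 300000, ">=300kb",
         sprintf("[%d,%d)kb", (len %/% 10000) * 10,
                 (len %/% 10000) * 10 + 10))
}

#' Length-stratified spatiotemporal binding profile
#'
#' TUs are stratified by length in 10-kb increments from 0 to 300 kb plus
#' one group for TUs of at least 300 kb. Each TU is segmented into 1-kb
#' bins progressing from the TSS to the TES (strand-aware, truncated at
#' the TES); per group, the mean weight per bin across member TUs is
#' divided by the group maximum, so each group's profile peaks at 1.
#'
#' @param track a normalized `site_track`.
#' @param annotation a `ticlip_annotation`.
#' @param read_scope `"all"` or `"intronic_only"` (restrict weights to
#'   intron-overlapping positions).
#' @return object of class `spatiotemporal_profiles`: a named list of
#'   groups, each with `profile` (group-max-normalized bin means),
#'   `raw_mean`, and `n_tu`; empty groups are omitted.
#' @export
spatiotemporal_matrix <- function(track, annotation,
                                  read_scope = c("all", "intronic_only")) {
  read_scope <- match.arg(read_scope)
  tus <- annotation$tus
  len <- tus$end - tus$start
  grp <- .length_group(len)
  by_cs <- split(seq_len(nrow(track)),
                 paste(track$chrom, track$strand, sep = "\r"))
  acc <- list()
  for (i in seq_len(nrow(tus))) {
    nb <- as.integer(ceiling(len[i] / 1000))
    idx <- by_cs[[paste(tus$chrom[i], tus$strand[i], sep = "\r")]]
    v <- numeric(nb)
    if (length(idx)) {
      p <- track$pos[idx]
      sel <- p >= tus$start[i] & p < tus$end[i]
      if (any(sel)) {
        ii <- idx[sel]
        if (read_scope == "intronic_only") {
          intr <- annotation$introns[annotation$introns$tu_id ==
                                       tus$tu_id[i], , drop = FALSE]
          if (nrow(intr)) {
            inside <- rep(FALSE, length(ii))
            for (r in seq_len(nrow(intr))) {
              inside <- inside | (track$pos[ii] >= intr$start[r] &
                                    track$pos[ii] < intr$end[r])
            }
            ii <- ii[inside]
          } else ii <- integer(0)
        }
        if (length(ii)) {
          off <- if (tus$strand[i] == "+") track$pos[ii] - tus$start[i]
                 else tus$end[i] - 1L - track$pos[ii]
          b <- pmin(off %/% 1000L + 1L, nb)
          v <- as.numeric(rowsum(track$weight[ii], b,
                                 reorder = TRUE)[
            match(seq_len(nb), sort(unique(b))), 1L])
          v[is.na(v)] <- 0
        }
      }
    }
    g <- grp[i]
    if (is.null(acc[[g]])) acc[[g]] <- list(sum = numeric(0), n = integer(0))
    nmax <- max(length(acc[[g]]$sum), nb)
    s <- c(acc[[g]]$sum, numeric(nmax - length(acc[[g]]$sum)))
    cnt <- c(acc[[g]]$n, integer(nmax - length(acc[[g]]$n)))
    s[seq_len(nb)] <- s[seq_len(nb)] + v
    cnt[seq_len(nb)] <- cnt[seq_len(nb)] + 1L
    acc[[g]] <- list(sum = s, n = cnt)
  }
  groups <- lapply(acc, function(a) {
    raw <- a$sum / pmax(a$n, 1L)
    mx <- max(raw)
    list(profile = if (mx > 0) raw / mx else raw, raw_mean = raw,
         n_tu = max(a$n))
  })
  # order groups by lower stratum bound
  ord <- order(vapply(names(groups), function(g) {
    if (g == ">=300kb") 300 else as.numeric(sub("^\\[(\\d+),.*$", "\\1", g))
  }, numeric(1)))
  structure(list(groups = groups[ord], read_scope = read_scope,
                 normalized = TRUE,
                 timepoint_label = attr(track, "timepoint_label")),
            class = "spatiotemporal_profiles")
}

#' Estimate the elongation-wave velocity from a profile time course
#'
#' The wave front at each timepoint is the largest 1-kb bin whose
#' moving-average-smoothed, group-max-normalized value reaches `tau`; the
#' velocity is the ordinary-least-squares slope of front position (kb)
#' versus minutes after release, fitted over the release timepoints only
#' (t = 0 and the steady-state library are excluded).
#'
#' @param profiles named list of `spatiotemporal_profiles`, one per
#'   timepoint.
#' @param minutes named numeric vector of minutes matching
#'   `names(profiles)`; `Inf` marks steady state.
#' @param group length-group label to read fronts from; default the
#'   longest group present in every timepoint.
#' @param tau front threshold on the normalized profile (default 0.1).
#' @param smooth_bins moving-average width in bins (default 3).
#' @return object of class `wave_estimate` with `velocity_kb_per_min`,
#'   `intercept_kb`, `front_kb_by_timepoint`, `r_squared`.
#' @export
estimate_wave_velocity <- function(profiles, minutes, group = NULL,
                                   tau = 0.1, smooth_bins = 3L) {
  stopifnot(all(names(profiles) %in% names(minutes)))
  if (is.null(group)) {
    common <- Reduce(intersect, lapply(profiles, function(p) names(p$groups)))
    if (!length(common)) stop("no length group shared by all timepoints")
    bound <- vapply(common, function(g) {
      if (g == ">=300kb") 300 else as.numeric(sub("^\\[(\\d+),.*$", "\\1", g))
    }, numeric(1))
    group <- common[which.max(bound)]
  }
  fronts <- vapply(profiles, function(p) {
    pr <- p$groups[[group]]$profile
    if (is.null(pr) || !any(pr > 0)) return(NA_real_)
    sm <- as.numeric(stats::filter(pr, rep(1 / smooth_bins, smooth_bins),
                                   sides = 2))
    sm[is.na(sm)] <- pr[is.na(sm)]
    hit <- which(sm >= tau)
    if (!length(hit)) NA_real_ else max(hit)
  }, numeric(1))
  mins <- minutes[names(profiles)]
  use <- is.finite(mins) & mins > 0 & !is.na(fronts)
  if (sum(use) < 3L) stop("need at least 3 usable release-timepoint fronts")
  fit <- stats::lm(fronts[use] ~ mins[use])
  structure(list(
    velocity_kb_per_min = unname(stats::coef(fit)[2L]),
    intercept_kb = unname(stats::coef(fit)[1L]),
    front_kb_by_timepoint = stats::setNames(fronts, names(profiles)),
    r_squared = summary(fit)$r.squared,
    group = group), class = "wave_estimate")
}

#' @export
print.wave_estimate <- function(x, ...) {
  cat("<wave_estimate> ", format(x$velocity_kb_per_min, digits = 3),
      " kb/min (R^2 = ", format(x$r_squared, digits = 3), ", group ",
      x$group, ")\n", sep = "")
  invisible(x)
}

# Exon table with genomic anchor of the chosen end, transcript-oriented.
.exon_anchor <- function(exons, tus, end) {
  m <- match(exons$tu_id, tus$tu_id)
  plus <- tus$strand[m] == "+"
  pos <- if (end == "3p") ifelse(plus, exons$end - 1L, exons$start)
         else ifelse(plus, exons$start, exons$end - 1L)
  data.frame(chrom = tus$chrom[m], strand = tus$strand[m], pos = pos)
}

#' Exon-end-anchored aggregate metagene profile
#'
#' Extracts a strand-oriented window centred on the 5' or 3' end of each
#' exon (offset 0 = the terminal exon nucleotide, negative = upstream in
#' transcript orientation), sums across exons and divides by the number of
#' contributing exons.
#'
#' @param track a `site_track`.
#' @param exons data.frame with `tu_id`, `start`, `end` (e.g. a subset of
#'   `annotation$exons`).
#' @param annotation the `ticlip_annotation` the exons belong to.
#' @param end `"5p"` or `"3p"`.
#' @param window odd window width (default 201).
#' @return named numeric vector of mean weights at offsets
#'   `-(window-1)/2 ... (window-1)/2`.
#' @export
exon_anchored_profile <- function(track, exons, annotation,
                                  end = c("3p", "5p"), window = 201L) {
  end <- match.arg(end)
  if (window %% 2L == 0L) stop("window must be odd")
  if (!nrow(exons)) stop("no exons supplied")
  a <- .exon_anchor(exons, annotation$tus, end)
  h <- (window - 1L) %/% 2L
  .window_aggregate(track, a$chrom, a$pos, a$strand, -h, h) / nrow(exons)
}

#' 3'CLIP signal around first-exon 3' ends
#'
#' Aggregates a 3'CLIP site track over an even window placed so that
#' offset 0 is the first exon's last nucleotide, and reports the
#' aggregate value at offset 0 — the signal of splicing intermediates
#' whose free 3'OH ends at the exon (5' splice site cleavage products).
#'
#' @param track a 3'CLIP `site_track`.
#' @param annotation a `ticlip_annotation`.
#' @param window even window width (default 76).
#' @return list with `profile` (named by offset, per contributing exon)
#'   and `at_zero`.
#' @export
three_prime_end_histogram <- function(track, annotation, window = 76L) {
  if (window %% 2L != 0L) stop("window must be even")
  ex <- annotation$exons
  n_ex <- stats::ave(ex$rank, ex$tu_id, FUN = max)
  first <- ex[ex$rank == 1L & n_ex > 1L, , drop = FALSE]
  if (!nrow(first)) stop("no first exons of multi-exonic TUs")
  a <- .exon_anchor(first, annotation$tus, "3p")
  h <- window %/% 2L
  prof <- .window_aggregate(track, a$chrom, a$pos, a$strand,
                            -h, h - 1L) / nrow(first)
  list(profile = prof, at_zero = unname(prof["0"]))
}

#' Binding density by exon rank category
#'
#' Reads/kb over the first 4 exons, the last 4 exons and any internal
#' exons of multi-exonic TUs (an exon of a short TU may belong to both a
#' `first` and a `last` category).
#'
#' @param track a `site_track`.
#' @param annotation a `ticlip_annotation`.
#' @return named numeric vector of densities for groups `first1..first4`,
#'   `last4..last1`, `internal`.
#' @export
exon_rank_density <- function(track, annotation) {
  ex <- annotation$exons
  tus <- annotation$tus
  n_ex <- stats::ave(ex$rank, ex$tu_id, FUN = max)
  multi <- n_ex > 1L
  ex <- ex[multi, , drop = FALSE]
  n_ex <- n_ex[multi]
  if (!nrow(ex)) stop("no multi-exonic TUs")
  m <- match(ex$tu_id, tus$tu_id)
  from_end <- n_ex - ex$rank + 1L
  reg <- list()
  add <- function(sel, g) {
    if (any(sel)) {
      reg[[length(reg) + 1L]] <<- data.frame(
        group = g, chrom = tus$chrom[m][sel], strand = tus$strand[m][sel],
        start = ex$start[sel], end = ex$end[sel], stringsAsFactors = FALSE)
    }
  }
  for (r in 1:4) add(ex$rank == r, paste0("first", r))
  for (r in 1:4) add(from_end == r, paste0("last", r))
  add(ex$rank > 4L & from_end > 4L, "internal")
  region_density(track, do.call(rbind, reg))
}

#' Mature-coordinate (exon-projected) binding profile of one TU
#'
#' Projects cross-link positions onto mature coordinates (exonic segments
#' concatenated in transcript orientation), bins the mature transcript
#' into 100 equal bins, and divides each bin by the TU total. TUs with a
#' mature length of at most 200 nt or at most 20 mapped reads are
#' excluded (strict filters).
#'
#' @param track a cross-link `site_track`.
#' @param annotation a `ticlip_annotation`.
#' @param tu_id one TU identifier.
#' @return list with `tu_id`, `excluded` (logical), `reason`
#'   (`"length"`/`"reads"`/`NA`), `n_reads`, `mature_length`, and
#'   `bin_values` (100 values summing to 1) when retained.
#' @export
mature_profile <- function(track, annotation, tu_id) {
  tus <- annotation$tus
  i <- match(tu_id, tus$tu_id)
  if (is.na(i)) stop("unknown TU: ", tu_id)
  ex <- annotation$exons[annotation$exons$tu_id == tu_id, , drop = FALSE]
  ex <- ex[order(ex$rank), , drop = FALSE]
  elen <- ex$end - ex$start
  M <- sum(elen)
  cum <- cumsum(c(0L, elen[-length(elen)]))
  sel <- track$chrom == tus$chrom[i] & track$strand == tus$strand[i]
  pos <- track$pos[sel]
  w <- track$weight[sel]
  mat_off <- rep(NA_integer_, length(pos))
  for (k in seq_len(nrow(ex))) {
    inside <- pos >= ex$start[k] & pos < ex$end[k]
    off_in_ex <- if (tus$strand[i] == "+") pos[inside] - ex$start[k]
                 else ex$end[k] - 1L - pos[inside]
    mat_off[inside] <- cum[k] + off_in_ex
  }
  keep <- !is.na(mat_off)
  n_reads <- sum(w[keep])
  if (M <= 200L) {
    return(list(tu_id = tu_id, excluded = TRUE, reason = "length",
                n_reads = n_reads, mature_length = M))
  }
  if (n_reads <= 20) {
    return(list(tu_id = tu_id, excluded = TRUE, reason = "reads",
                n_reads = n_reads, mature_length = M))
  }
  b <- pmin(mat_off[keep] %/% (M / 100), 99) + 1L
  bins <- numeric(100)
  agg <- rowsum(w[keep], b)
  bins[as.integer(rownames(agg))] <- agg[, 1L]
  list(tu_id = tu_id, excluded = FALSE, reason = NA_character_,
       n_reads = n_reads, mature_length = M, bin_values = bins / n_reads)
}

#' Mature profiles of all retained TUs as a matrix
#'
#' @inheritParams mature_profile
#' @return matrix (retained TUs x 100 bins); excluded TU ids and reasons
#'   are attached as attribute `excluded`.
#' @export
mature_profile_matrix <- function(track, annotation) {
  res <- lapply(annotation$tus$tu_id, function(id) {
    mature_profile(track, annotation, id)
  })
  kept <- Filter(function(r) !r$excluded, res)
  excl <- Filter(function(r) r$excluded, res)
  m <- do.call(rbind, lapply(kept, `[[`, "bin_values"))
  if (!is.null(m)) rownames(m) <- vapply(kept, `[[`, character(1), "tu_id")
  attr(m, "excluded") <- data.frame(
    tu_id = vapply(excl, `[[`, character(1), "tu_id"),
    reason = vapply(excl, `[[`, character(1), "reason"))
  m
}

# mature-coordinate bin of positions p on a transcript of length M
.mature_bin <- function(p, M) pmin(as.integer(p %/% (M / 100)), 99L) + 1L

#' Cluster mature binding profiles across replicates
#'
#' Runs k-means (Euclidean, on the raw 100-bin profiles) independently per
#' biological replicate, matches clusters across replicates by greedy
#' maximal centroid cosine similarity, and retains a TU in a final group
#' only if it was assigned to the matched cluster in every replicate.
#' The largest final group is treated as the unstructured background and
#' is dropped from `groups` unless `report_background = TRUE`; reported
#' groups are ordered by descending cap-proximal (first 25 bins) centroid
#' mass, so `group1` is the most 5'-enriched profile.
#'
#' @param profiles named list of replicate matrices (TUs x 100 bins) with
#'   identical row sets.
#' @param k number of centres (default 3).
#' @param seed RNG seed (k-means uses `nstart` restarts per replicate).
#' @param nstart k-means restarts (default 10).
#' @param report_background also report the background group.
#' @return object of class `cluster_groups`: `groups` (named list of TU id
#'   vectors), `background` (TU ids), `assignments` (per-replicate cluster
#'   table), `centroids` (matched, replicate-averaged).
#' @export
kmeans_profile_groups <- function(profiles, k = 3L, seed = 1L,
                                  nstart = 10L, report_background = FALSE) {
  if (length(profiles) < 2L) stop("need at least 2 replicates")
  ids <- rownames(profiles[[1L]])
  for (p in profiles) {
    if (!identical(sort(rownames(p)), sort(ids))) {
      stop("every TU must be present in all replicates")
    }
  }
  if (k > nrow(profiles[[1L]])) stop("k exceeds the number of profiles")
  fits <- vector("list", length(profiles))
  for (r in seq_along(profiles)) {
    set.seed(.sub_seed(seed, r))
    fits[[r]] <- stats::kmeans(profiles[[r]][ids, , drop = FALSE],
                               centers = k, nstart = nstart,
                               iter.max = 50L)
  }
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  # greedy cluster matching against replicate 1
  maps <- vector("list", length(profiles))
  maps[[1L]] <- seq_len(k)
  for (r in seq_along(profiles)[-1L]) {
    sim <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      cosine(fits[[1L]]$centers[i, ], fits[[r]]$centers[j, ])
    }))
    map <- integer(k)
    for (s in seq_len(k)) {
      best <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
      map[best[2L]] <- best[1L]
      sim[best[1L], ] <- -Inf
      sim[, best[2L]] <- -Inf
    }
    maps[[r]] <- map    # cluster j in rep r corresponds to map[j] in rep 1
  }
  asg <- vapply(seq_along(profiles), function(r) {
    maps[[r]][fits[[r]]$cluster[ids]]
  }, integer(length(ids)))
  final <- ifelse(apply(asg, 1L, function(v) all(v == v[1L])),
                  asg[, 1L], NA_integer_)
  members <- split(ids[!is.na(final)], final[!is.na(final)])
  sizes <- vapply(members, length, integer(1))
  background_cl <- names(sizes)[which.max(sizes)]
  centroids <- t(vapply(names(members), function(g) {
    colMeans(do.call(rbind, lapply(seq_along(profiles), function(r) {
      fits[[r]]$centers[match(as.integer(g), maps[[r]]), ]
    })))
  }, numeric(ncol(profiles[[1L]]))))
  report <- names(members)
  if (!report_background) report <- setdiff(report, background_cl)
  cap_mass <- vapply(report, function(g) {
    sum(centroids[g, 1:25])
  }, numeric(1))
  report <- report[order(-cap_mass)]
  groups <- stats::setNames(members[report],
                            paste0("group", seq_along(report)))
  structure(list(groups = groups, background = members[[background_cl]],
                 assignments = data.frame(tu_id = ids, asg,
                                          final = final),
                 centroids = centroids),
            class = "cluster_groups")
}

#' @export
print.cluster_groups <- function(x, ...) {
  cat("<cluster_groups> ", length(x$groups), " reported group(s): ",
      paste(sprintf("%s (n=%d)", names(x$groups),
                    lengths(x$groups)), collapse = ", "),
      "; background n=", length(x$background), "\n", sep = "")
  invisible(x)
}

#' Average exon-junction density profile of a TU group
#'
#' Places each TU's exon-exon junction positions in mature coordinates,
#' bins them into 100 bins, normalizes per TU by its junction count, and
#' averages over the group. Mono-exonic TUs contribute zeros.
#'
#' @param annotation a `ticlip_annotation`.
#' @param tu_ids TU identifiers of the group.
#' @return numeric vector of 100 average junction densities.
#' @export
junction_density_profile <- function(annotation, tu_ids) {
  prof <- vapply(tu_ids, function(id) {
    ex <- annotation$exons[annotation$exons$tu_id == id, , drop = FALSE]
    ex <- ex[order(ex$rank), , drop = FALSE]
    v <- numeric(100)
    if (nrow(ex) > 1L) {
      elen <- ex$end - ex$start
      M <- sum(elen)
      jx <- cumsum(elen)[-nrow(ex)]
      b <- .mature_bin(jx, M)
      for (bb in b) v[bb] <- v[bb] + 1 / length(jx)
    }
    v
  }, numeric(100))
  rowMeans(prof)
}
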