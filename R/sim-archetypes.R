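#' Simulate planted mature-profile archetypes across replicates
#'
#' Generates per-replicate 100-bin mature binding profiles for a planted
#' two-archetype population, mirroring the two recurrent metagene shapes
#' of cap-binding-adjacent export factors: archetype A has strong 5'-end
#' enrichment with a slight additional 3'-end bump, archetype B only
#' 3'-end enrichment; the remaining TUs are unstructured noise profiles.
#' Each profile is a multinomial draw of `reads_per_tu` reads from the
#' archetype density, normalized to sum to 1 — the same shape
#' [mature_profile()] produces.
#'
#' @param n_a,n_b,n_noise TU counts per archetype and for the noise pool.
#' @param n_replicates number of replicate matrices (default 2).
#' @param reads_per_tu multinomial read depth per TU (default 200).
#' @param seed RNG seed.
#' @return list with `profiles` (list of replicate matrices, rows
#'   `tuA*`/`tuB*`/`tuN*`), and `truth` (named archetype vector).
#' @export
simulate_profile_archetypes <- function(n_a = 60L, n_b = 60L,
                                        n_noise = 120L, n_replicates = 2L,
                                        reads_per_tu = 200L, seed = 1L) {
  set.seed(.sub_seed(seed, 97L))
  dens_a <- c(rep(0.07, 10), rep(0.1 / 80, 80), rep(0.02, 10))
  dens_b <- c(rep(0.2 / 90, 90), rep(0.08, 10))
  ids <- c(sprintf("tuA%03d", seq_len(n_a)),
           sprintf("tuB%03d", seq_len(n_b)),
           sprintf("tuN%03d", seq_len(n_noise)))
  truth <- stats::setNames(rep(c("A", "B", "noise"),
                               c(n_a, n_b, n_noise)), ids)
  draw <- function(dens) {
    as.numeric(stats::rmultinom(1L, reads_per_tu, dens)) / reads_per_tu
  }
  profiles <- lapply(seq_len(n_replicates), function(r) {
    m <- t(vapply(ids, function(id) {
      if (startsWith(id, "tuA")) draw(dens_a)
      else if (startsWith(id, "tuB")) draw(dens_b)
      else draw(stats::runif(100, 0.5, 1.5))
    }, numeric(100)))
    rownames(m) <- ids
    m
  })
  list(profiles = profiles, truth = truth)
}
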