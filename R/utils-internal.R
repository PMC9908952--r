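# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; conversion to/from 1-based happens only at
# the rtracklayer/Rsamtools boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Block lists are stored as comma-joined integer strings so that an
# aligned-pair table stays a flat data.frame (fast to subset, trivial to
# round-trip). Most operations only need the first/last coordinate, which
# these helpers extract without a strsplit.
.pack_ints <- function(x) {
  vapply(x, function(v) paste(as.integer(v), collapse = ","), character(1),
         USE.NAMES = FALSE)
}

.unpack_ints <- function(s) {
  out <- strsplit(as.character(s), ",", fixed = TRUE)
  lapply(out, function(v) as.integer(v[nzchar(v)]))
}

.first_int <- function(s) {
  out <- suppressWarnings(as.integer(sub(",.*$", "", s)))
  out
}

.last_int <- function(s) {
  out <- suppressWarnings(as.integer(sub("^.*,", "", s)))
  out
}

.strand_sign <- function(strand) ifelse(strand == "+", 1L, -1L)

.check_strand <- function(strand) {
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    stop("strand must be '+' or '-' (got '", strand[which(bad)[1]],
         "'); '.' is not allowed", call. = FALSE)
  }
  invisible(strand)
}

.random_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# Deterministic small sub-seed derivation that stays inside 32-bit range.
.sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
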