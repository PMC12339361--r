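# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the package's optimised code paths.

# Exhaustive Hamming scan of a query against every library detection
# sequence, applying the tiered zero/one-mismatch, no-ambiguity rule.
brute_force_match <- function(seq, lib, read_length) {
  prefixes <- substr(lib$detect_seq, 1, read_length)
  qs <- strsplit(seq, "")[[1]]
  d <- vapply(prefixes, function(p) {
    sum(strsplit(p, "")[[1]] != qs)
  }, integer(1), USE.NAMES = FALSE)
  hit0 <- which(d == 0L)
  if (length(hit0) >= 1L) {
    if (length(hit0) > 1L || lib$duplicate[hit0]) {
      return(list(status = "ambiguous", guide_id = NA_character_,
                  distance = 0L))
    }
    return(list(status = "exact", guide_id = lib$guide_id[hit0],
                distance = 0L))
  }
  hit1 <- which(d == 1L)
  if (length(hit1) == 0L) {
    return(list(status = "unmatched", guide_id = NA_character_,
                distance = NA_integer_))
  }
  if (length(hit1) > 1L || any(lib$duplicate[hit1])) {
    return(list(status = "ambiguous", guide_id = NA_character_,
                distance = 1L))
  }
  list(status = "corrected", guide_id = lib$guide_id[hit1], distance = 1L)
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(m+n, m) group assignments of the pooled sample.
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(ix) {
    sum(r[ix]) - m * (m + 1) / 2
  })
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Literal step-up Benjamini-Hochberg.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Direct windowed sum of a high-pass-filtered channel around one spot;
# mirrors the extraction definition without sharing its code.
window_sum_oracle <- function(image, row0, col0, window, sigma) {
  blur <- EBImage::imageData(EBImage::gblur(EBImage::Image(image),
                                            sigma = sigma))
  hp <- pmax(image - blur, 0)
  half <- (window - 1) %/% 2
  rr <- max(1, row0 + 1 - half):min(nrow(image), row0 + 1 + half)
  cc <- max(1, col0 + 1 - half):min(ncol(image), col0 + 1 + half)
  sum(hp[rr, cc])
}

# Tiny deterministic library for unit tests.
toy_library <- function(n = 6L, L = 8L, seed = 42L) {
  simulate_library(n_genes = max(1L, n - 1L), guides_per_gene = 1L,
                   n_nt = 1L, L = L, seed = seed)
}

# A minimal spot profile tibble from a list of C x 3 unmixed matrices.
profiles_from_unmixed <- function(unmixed_list) {
  tibble::tibble(
    spot_id = seq_along(unmixed_list),
    unmixed = unmixed_list,
    max_unmixed = vapply(unmixed_list, max, numeric(1))
  )
}
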