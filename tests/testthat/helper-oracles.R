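# Independent brute-force oracles, deliberately written with different
# algorithms from the package implementations they check.

# O(n^2) transitive-merge clustering: any two peaks whose gap is within
# tol ppm of the lower m/z are linked, and clusters are the transitive
# closure of the full pairwise adjacency matrix (no sorting, no gap
# insight). Returns a partition label per peak, in input order.
oracle_cluster <- function(mz, tol_ppm) {
  lo <- outer(mz, mz, pmin)
  hi <- outer(mz, mz, pmax)
  reach <- (hi - lo) <= tol_ppm * lo * 1e-6
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  keys <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  match(keys, unique(keys))
}

canonical_partition <- function(labels) {
  # membership sets sorted, independent of label numbering
  s <- split(seq_along(labels), labels)
  s <- lapply(s, sort)
  s[order(vapply(s, `[`, integer(1), 1))]
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n1+n2, n1) group assignments of the pooled ranks.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# BH step-up from the definition: adj_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Tiny spectra/section builders used across test files.
spec_of <- function(mz, int = rep(1, length(mz))) msi_spectrum(mz, int)

section_of <- function(spectra, nx = length(spectra), ny = 1,
                       id = "sec", ...) {
  msi_section(spectra,
              coords = data.frame(x = seq_along(spectra), y = 1L),
              grid_shape = c(ny, nx), section_id = id, ...)
}

fm_of <- function(values, feature_mz = NULL, section_id = "sec",
                  region = NULL, treatment = NULL, time_h = NULL) {
  n <- nrow(values)
  if (is.null(feature_mz)) feature_mz <- 100 + seq_len(ncol(values))
  meta <- data.frame(section_id = rep_len(section_id, n),
                     x = seq_len(n), y = 1L,
                     time_point_h = if (is.null(time_h)) NA_real_
                     else rep_len(time_h, n),
                     treatment = if (is.null(treatment)) NA_character_
                     else rep_len(treatment, n))
  if (!is.null(region)) meta$region_label <- rep_len(region, n)
  feature_matrix(feature_mz, values, meta, validate = FALSE)
}
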