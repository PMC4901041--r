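#' Expected fragment-size distribution under uniform random breakage
#'
#' Analytic per-bin expectation for a circular plasmid of length `L`
#' receiving `Poisson(mu)` breaks placed uniformly. Conditional on `k >= 2`
#' breaks, each fragment length has density
#' `f(x|k) = ((k-1)/L) (1 - x/L)^(k-2)` on `(0, L)` with CDF
#' `F(x|k) = 1 - (1 - x/L)^(k-1)`; a single break contributes a point mass
#' at `L` (a full-length linear fragment). The expectation per bin mixes over
#' the break count,
#' `E[bin] = sum_k P(K=k) * k * (F(b|k) - F(a|k))`,
#' with the Poisson sum truncated where its remaining tail mass drops below
#' `tail_tol`. Summed over all bins the expectation equals `mu` (each break
#' makes one fragment); for large `mu` the profile approaches the
#' exponential `mu/L * exp(-mu x / L)` scaled to `mu` fragments — the
#' familiar near-exponential low-LET size distribution.
#'
#' @param mu mean breaks per plasmid (non-negative).
#' @param L plasmid contour length in nm.
#' @param w bin width in nm; must divide `L`.
#' @param tail_tol Poisson tail mass at which the mixture sum is truncated.
#' @return An object of class `uniform_null_expectation`: `mu`, `bin_edges`,
#'   `expected_per_bin` (expected fragments per plasmid per bin),
#'   `expected_dsb_per_dna`.
#' @export
uniform_null_bin_expectation <- function(mu, L = 850, w = 50, tail_tol = 1e-12) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a single finite number >= 0", call. = FALSE)
  }
  nb <- L / w
  if (!is.numeric(L) || L <= 0 || !is.numeric(w) || w <= 0 ||
      abs(nb - round(nb)) > 1e-9) {
    stop("`w` must be positive and divide `L`", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  edges <- seq(0, L, by = w)
  expected <- numeric(nb)
  if (mu > 0) {
    kmax <- max(2L, as.integer(stats::qpois(tail_tol, mu, lower.tail = FALSE)) + 5L)
    pk <- stats::dpois(seq_len(kmax), mu)
    expected[nb] <- pk[1]                      # k = 1: point mass at L
    for (k in 2:kmax) {
      cdf <- 1 - (1 - edges / L)^(k - 1)
      expected <- expected + pk[k] * k * diff(cdf)
    }
  }
  structure(
    list(mu = mu, bin_edges = edges, expected_per_bin = expected,
         expected_dsb_per_dna = sum(expected), bin_width = w, L = L),
    class = "uniform_null_expectation"
  )
}

#' @export
print.uniform_null_expectation <- function(x, ...) {
  cat(sprintf("<uniform_null_expectation> mu = %.4g over %d x %g nm bins (sum %.6g)\n",
              x$mu, length(x$expected_per_bin), x$bin_width,
              sum(x$expected_per_bin)))
  invisible(x)
}

#' Method-of-moments break-rate estimate
#'
#' Under the uniform model the expected number of fragments per molecule is
#' `mu`, so the observed DSB/DNA is the natural estimator of the break rate.
#'
#' @inheritParams bin_fragments
#' @return Estimated mean breaks per plasmid; 0 for an all-circular sample.
#' @export
estimate_break_rate <- function(records, L) {
  dsb_per_dna(records, L)
}

#' Clustering index: short-fragment excess over the uniform null
#'
#' The ratio of the observed DSB density in the shortest bin(s) to the
#' uniform-null expectation at the same overall break rate. Near 1 for
#' uniformly placed breaks; well above 1 when breaks arrive in spatial
#' clusters, which pile fragments into the shortest length bin. The null
#' must be evaluated at `mu` equal to the sample's observed DSB/DNA.
#'
#' @param profile a [spatial_dsb_profile()].
#' @param null a [uniform_null_bin_expectation()] computed at the sample's
#'   DSB/DNA and the same binning.
#' @param bins number of leading bins to pool (default 1, the `(0, w]` bin).
#' @return An object of class `clustering_index`: `observed_first_bin`,
#'   `expected_first_bin_null`, `index`, `bins`.
#' @export
clustering_index <- function(profile, null, bins = 1L) {
  if (!inherits(profile, "spatial_dsb_profile")) {
    stop("`profile` must be a spatial_dsb_profile", call. = FALSE)
  }
  if (!inherits(null, "uniform_null_expectation")) {
    stop("`null` must be a uniform_null_expectation", call. = FALSE)
  }
  if (length(profile$dsb_per_dna_per_bin) != length(null$expected_per_bin) ||
      profile$bin_width != null$bin_width) {
    stop("profile and null use different binning", call. = FALSE)
  }
  if (abs(null$mu - profile$dsb_per_dna) > 0.05 * max(profile$dsb_per_dna, 1)) {
    warning("null was not evaluated at the sample's DSB/DNA; the index is biased",
            call. = FALSE)
  }
  bins <- as.integer(bins)
  if (bins < 1L || bins > length(null$expected_per_bin)) {
    stop("`bins` out of range", call. = FALSE)
  }
  obs <- sum(profile$dsb_per_dna_per_bin[seq_len(bins)])
  expct <- sum(null$expected_per_bin[seq_len(bins)])
  if (expct <= 0) {
    stop("null expectation in the leading bin(s) is zero: index undefined",
         call. = FALSE)
  }
  structure(
    list(observed_first_bin = obs, expected_first_bin_null = expct,
         index = obs / expct, bins = bins),
    class = "clustering_index"
  )
}

#' @export
print.clustering_index <- function(x, ...) {
  cat(sprintf("<clustering_index> observed %.4g vs null %.4g in first %d bin(s): index %.3f\n",
              x$observed_first_bin, x$expected_first_bin_null, x$bins, x$index))
  invisible(x)
}

#' One-call model fit for a fragment sample
#'
#' Convenience wrapper: estimates the break rate, computes the spatial
#' profile and the matching uniform null, and returns the clustering index
#' with per-bin observed and expected values.
#'
#' @inheritParams bin_fragments
#' @return A list with `mu_hat`, `clustering_index`, `observed_per_bin`
#'   (DSB/DNA per bin), `expected_per_bin` (null), `bin_edges`.
#' @export
fit_breakage <- function(records, L, w = 50) {
  records <- as_fragment_records(records)
  mu_hat <- estimate_break_rate(records, L)
  prof <- spatial_dsb_profile(records, L, w)
  null <- uniform_null_bin_expectation(mu_hat, L, w)
  ci <- clustering_index(prof, null)
  list(mu_hat = mu_hat,
       clustering_index = ci$index,
       observed_per_bin = prof$dsb_per_dna_per_bin,
       expected_per_bin = null$expected_per_bin,
       bin_edges = prof$bin_edges)
}
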