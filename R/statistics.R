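#' Build a fragment-record table
#'
#' The canonical container for measured DNA pieces: one row per fragment (or
#' intact circle) with its contour length in nm and topology. All analysis
#' functions accept this data.frame, a [simulate_sample()] result, or a bare
#' numeric vector of linear fragment lengths.
#'
#' @param length_nm fragment contour lengths in nm (positive).
#' @param topology `"linear"` or `"circular"`, recycled to match.
#' @param sample_id sample label, recycled.
#' @return A data.frame with columns `sample_id`, `fragment_id`,
#'   `length_nm`, `topology`.
#' @export
fragment_records <- function(length_nm, topology = "linear", sample_id = "sample") {
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), length(length_nm)),
    fragment_id = seq_along(length_nm),
    length_nm = as.numeric(length_nm),
    topology = rep_len(as.character(topology), length(length_nm)),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

#' Coerce to fragment records
#'
#' @param x a fragment-record data.frame, a `sample_measurement`, or a
#'   numeric vector of linear fragment lengths.
#' @param ... unused.
#' @return A validated fragment-record data.frame.
#' @export
as_fragment_records <- function(x, ...) UseMethod("as_fragment_records")

#' @export
as_fragment_records.sample_measurement <- function(x, ...) x$records

#' @export
as_fragment_records.data.frame <- function(x, ...) validate_records(x)

#' @export
as_fragment_records.numeric <- function(x, ...) fragment_records(x)

#' @export
as_fragment_records.default <- function(x, ...) {
  stop("cannot interpret `x` as fragment records", call. = FALSE)
}

# Column and value checks shared by every analysis entry point. Topology is
# required, never guessed: a full-length linear fragment and an intact
# circle have the same contour length but count differently.
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame", call. = FALSE)
  need <- c("length_nm", "topology")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records are missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(records$length_nm) || any(!is.finite(records$length_nm)) ||
      any(records$length_nm <= 0)) {
    stop("all `length_nm` values must be finite and > 0", call. = FALSE)
  }
  bad <- !(records$topology %in% c("linear", "circular"))
  if (any(bad)) {
    stop("invalid topology value(s): ",
         paste(unique(records$topology[bad]), collapse = ", "),
         " (must be 'linear' or 'circular')", call. = FALSE)
  }
  if (is.null(records$sample_id)) records$sample_id <- "sample"
  records
}

# Measurement-noise policy against the physical ceiling L: lengths at most
# 2% above L are clamped to L (warning); anything larger is reported and
# excluded from analysis.
clamp_to_plasmid <- function(records, L, tol_frac = 0.02) {
  over <- records$length_nm > L
  if (!any(over)) return(records)
  hopeless <- records$length_nm > L * (1 + tol_frac)
  if (any(hopeless)) {
    warning(sprintf("%d record(s) exceed the intact length %g nm by more than %g%% and were excluded",
                    sum(hopeless), L, 100 * tol_frac), call. = FALSE)
    records <- records[!hopeless, , drop = FALSE]
    over <- records$length_nm > L
  }
  if (any(over)) {
    warning(sprintf("%d record(s) slightly exceed the intact length %g nm and were clamped",
                    sum(over), L), call. = FALSE)
    records$length_nm[over] <- L
  }
  records
}

# Compensated (chunked long-double + Neumaier) summation so that total DNA
# length, and hence the molecule count, is exact on noise-free data.
compensated_sum <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  chunk <- 4096L
  if (n > chunk) {
    nch <- as.integer(ceiling(n / chunk))
    m <- matrix(c(x, numeric(nch * chunk - n)), nrow = chunk)
    x <- colSums(m)
  }
  s <- 0
  comp <- 0
  for (xi in x) {
    t <- s + xi
    comp <- comp + if (abs(s) >= abs(xi)) (s - t) + xi else (xi - t) + s
    s <- t
  }
  s + comp
}

#' Fragment-size distribution in fixed-width bins
#'
#' Bins the linear fragment lengths into `L/w` equal bins over `(0, L]`
#' (default 50 nm bins over 0–850 nm, seventeen bins). Bins are left-open,
#' right-closed — `(0,50], (50,100], ..., (800,850]` — so a full-length
#' linear fragment falls in the last bin. Intact circular records are not
#' fragments and are not binned.
#'
#' @param records fragment records (see [as_fragment_records()]).
#' @param L intact plasmid contour length in nm.
#' @param w bin width in nm; must divide `L`.
#' @return An object of class `size_distribution`: `bin_edges` (length
#'   `L/w + 1`), `counts`, `n_fragments`, `rel_freq`, `bin_width`, `L`.
#' @export
bin_fragments <- function(records, L, w = 50) {
  records <- as_fragment_records(records)
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  nb <- L / w
  if (!is.numeric(w) || length(w) != 1L || w <= 0 || abs(nb - round(nb)) > 1e-9) {
    stop("`w` must be positive and divide `L`", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  records <- clamp_to_plasmid(records, L)
  x <- records$length_nm[records$topology == "linear"]
  idx <- as.integer(ceiling(x / w))
  counts <- tabulate(idx, nbins = nb)
  n <- length(x)
  structure(
    list(bin_edges = seq(0, L, by = w),
         counts = counts,
         n_fragments = n,
         rel_freq = if (n > 0) counts / n else rep(0, nb),
         bin_width = w,
         L = L),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d linear fragments in %d x %g nm bins over (0, %g]\n",
              x$n_fragments, length(x$counts), x$bin_width, x$L))
  df <- data.frame(bin = sprintf("(%g,%g]", x$bin_edges[-length(x$bin_edges)],
                                 x$bin_edges[-1]),
                   count = x$counts, rel_freq = round(x$rel_freq, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Number of DNA molecules represented by a fragment set
#'
#' Total length conservation: cutting never changes total contour length, so
#' the number of plasmid equivalents in a sample is the sum of all measured
#' lengths (circles included) divided by the intact length `L`. Summation is
#' compensated, so on noise-free simulated data the result equals the
#' simulated plasmid count exactly.
#'
#' @inheritParams bin_fragments
#' @return Number of molecules (real; 0 for empty input).
#' @export
count_molecules <- function(records, L) {
  records <- as_fragment_records(records)
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  if (nrow(records) == 0L) return(0)
  records <- clamp_to_plasmid(records, L)
  compensated_sum(records$length_nm) / L
}

#' DSBs per DNA molecule
#'
#' Each double-strand break adds exactly one fragment, so DSB/DNA is the
#' number of linear fragments divided by the number of molecules — intact
#' circles count in the denominator only.
#'
#' @inheritParams bin_fragments
#' @return DSB per DNA molecule (real, >= 0).
#' @export
dsb_per_dna <- function(records, L) {
  records <- as_fragment_records(records)
  m <- count_molecules(records, L)
  if (m <= 0) stop("zero molecules: DSB/DNA is undefined for empty input", call. = FALSE)
  sum(records$topology == "linear") / m
}

#' DSBs per broken DNA molecule
#'
#' As [dsb_per_dna()] but restricted to fragmented molecules: linear
#' fragment count divided by the plasmid equivalents of the linear material
#' only. Always at least 1 when any fragment exists, and at least
#' `dsb_per_dna` when intact circles are present.
#'
#' @inheritParams bin_fragments
#' @return DSB per broken DNA molecule.
#' @export
dsb_per_broken_dna <- function(records, L) {
  records <- as_fragment_records(records)
  records <- clamp_to_plasmid(records, L)
  lin <- records$length_nm[records$topology == "linear"]
  if (length(lin) == 0L) {
    stop("no linear fragments: DSB per broken DNA is undefined", call. = FALSE)
  }
  length(lin) / (compensated_sum(lin) / L)
}

#' Spatial DSB profile
#'
#' DSBs per DNA molecule attributed to each fragment-length interval: the
#' per-bin linear fragment count divided by the total molecule count (same
#' denominator as [dsb_per_dna()], so the profile sums to DSB/DNA). A
#' concentration in the shortest bin indicates spatially clustered breaks.
#'
#' @inheritParams bin_fragments
#' @return An object of class `spatial_dsb_profile`: `bin_edges`,
#'   `dsb_per_dna_per_bin`, `dsb_per_dna`, `n_molecules`, `bin_width`, `L`.
#' @export
spatial_dsb_profile <- function(records, L, w = 50) {
  records <- as_fragment_records(records)
  dist <- bin_fragments(records, L, w)
  m <- count_molecules(records, L)
  if (m <= 0) stop("zero molecules: spatial profile is undefined", call. = FALSE)
  structure(
    list(bin_edges = dist$bin_edges,
         dsb_per_dna_per_bin = dist$counts / m,
         dsb_per_dna = dist$n_fragments / m,
         n_molecules = m,
         bin_width = dist$bin_width,
         L = L),
    class = "spatial_dsb_profile"
  )
}

#' Bootstrap standard deviation of DSB/DNA
#'
#' Nonparametric bootstrap over fragment records: resamples the record table
#' with replacement `B` times, recomputes DSB/DNA for each resample, and
#' returns the standard deviation. Deterministic given `seed`; the caller's
#' RNG state is untouched.
#'
#' @inheritParams bin_fragments
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @return Bootstrap standard deviation of the DSB/DNA estimate.
#' @export
bootstrap_std <- function(records, L, B = 1000, seed = 1) {
  records <- as_fragment_records(records)
  records <- clamp_to_plasmid(records, L)
  n <- nrow(records)
  if (n < 2L) stop("bootstrap requires at least 2 records", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || B < 2 || B != round(B)) {
    stop("`B` must be a single integer >= 2", call. = FALSE)
  }
  B <- as.integer(B)
  len <- records$length_nm
  lin <- as.numeric(records$topology == "linear")
  stat <- numeric(B)
  chunk <- max(1L, as.integer(floor(2e7 / n)))
  with_seed(seed, {
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
      n_lin <- colSums(matrix(lin[idx], nrow = n))
      mol <- colSums(matrix(len[idx], nrow = n)) / L
      stat[(done + 1L):(done + b)] <- n_lin / mol
      done <- done + b
    }
  })
  stats::sd(stat)
}

#' Full DSB summary for one sample
#'
#' Aggregates molecule counts, DSB/DNA, DSB per broken DNA, and the
#' bootstrap uncertainty into one object (the per-sample summary a results
#' table is built from).
#'
#' @inheritParams bootstrap_std
#' @return An object of class `dsb_stats`: `n_fragments`, `n_molecules`,
#'   `n_broken_molecules`, `dsb_per_dna`, `dsb_per_broken_dna`, `std`.
#' @export
dsb_stats <- function(records, L, B = 1000, seed = 1) {
  records <- as_fragment_records(records)
  records <- clamp_to_plasmid(records, L)
  lin <- records$topology == "linear"
  m <- count_molecules(records, L)
  if (m <= 0) stop("zero molecules: DSB statistics are undefined", call. = FALSE)
  n_broken <- compensated_sum(records$length_nm[lin]) / L
  per_broken <- if (any(lin)) sum(lin) / n_broken else {
    warning("no linear fragments: DSB per broken DNA reported as NA", call. = FALSE)
    NA_real_
  }
  std <- if (nrow(records) >= 2L) bootstrap_std(records, L, B = B, seed = seed)
         else NA_real_
  structure(
    list(n_fragments = sum(lin),
         n_molecules = m,
         n_broken_molecules = n_broken,
         dsb_per_dna = sum(lin) / m,
         dsb_per_broken_dna = per_broken,
         std = std,
         bootstrap_B = B,
         seed = seed,
         L = L),
    class = "dsb_stats"
  )
}

#' @export
print.dsb_stats <- function(x, ...) {
  cat("<dsb_stats>\n")
  cat(sprintf("  fragments: %d, molecules: %.4f (broken: %.4f)\n",
              x$n_fragments, x$n_molecules, x$n_broken_molecules))
  cat(sprintf("  DSB/DNA: %.2f +/- %.2f (bootstrap, B = %d)\n",
              x$dsb_per_dna, x$std, x$bootstrap_B))
  cat(sprintf("  DSB/broken DNA: %.2f\n", x$dsb_per_broken_dna))
  invisible(x)
}

#' Relative biological effectiveness for DSB induction
#'
#' RBE is the ratio of DSB per DNA molecule under a test radiation to that
#' under the reference radiation (Co-60 in the bundled table). The
#' uncertainty combines the two relative errors in quadrature, treating the
#' estimates as independent:
#' `std = sqrt((std_test/dsb_ref)^2 + (dsb_test * std_ref / dsb_ref^2)^2)`.
#' Values are held at full precision; printing rounds to 2 decimals.
#'
#' @param dsb_test,dsb_ref DSB/DNA of the test and reference radiation
#'   (reference must be positive).
#' @param std_test,std_ref their standard deviations (non-negative).
#' @param test_label,reference_label optional labels.
#' @return An object of class `rbe_result`: `rbe`, `std`, `test_label`,
#'   `reference_label`.
#' @examples
#' compute_rbe(4.77, 0.4, 5.83, 0.33)  # RBE 0.82 +/- 0.08
#' @export
compute_rbe <- function(dsb_test, std_test, dsb_ref, std_ref,
                        test_label = "test", reference_label = "reference") {
  vals <- c(dsb_test, std_test, dsb_ref, std_ref)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("all inputs must be finite numbers", call. = FALSE)
  }
  if (dsb_ref <= 0) stop("reference DSB/DNA must be positive", call. = FALSE)
  if (dsb_test < 0) stop("test DSB/DNA must be non-negative", call. = FALSE)
  if (std_test < 0 || std_ref < 0) stop("standard deviations must be >= 0", call. = FALSE)
  rbe <- dsb_test / dsb_ref
  std <- sqrt((std_test / dsb_ref)^2 + (dsb_test * std_ref / dsb_ref^2)^2)
  structure(
    list(rbe = rbe, std = std,
         test_label = test_label, reference_label = reference_label),
    class = "rbe_result"
  )
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("<rbe_result> %s vs %s: RBE %.2f +/- %.2f\n",
              x$test_label, x$reference_label, x$rbe, x$std))
  invisible(x)
}
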