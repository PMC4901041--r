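#' Uniform (low-LET) breakage model
#'
#' Random-breakage null: each plasmid receives `K ~ Poisson(mu)` double-strand
#' breaks placed independently and uniformly on the circle. This is the
#' standard model for sparsely ionising (photon, electron) radiation.
#'
#' @param mu mean number of DSBs per plasmid (non-negative).
#' @return An object of class `uniform_break_model`.
#' @export
uniform_break_model <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu)), class = c("uniform_break_model", "break_model"))
}

#' Clustered (high-LET) breakage model
#'
#' Compound-Poisson two-scale process emulating densely ionising particle
#' tracks: the number of tracks hitting a plasmid is `Poisson(track_rate)`;
#' each track draws a cluster size (breaks per track) from
#' `cluster_size_law` and places those breaks uniformly within a window of
#' width `cluster_span_nm` centred at a uniform position on the circle
#' (wrapping at the origin). Mean breaks per plasmid is
#' `track_rate * mean_cluster_size(cluster_size_law)`.
#'
#' @param track_rate mean number of tracks per plasmid (non-negative).
#' @param cluster_size_law discrete distribution of breaks per track, e.g.
#'   [cluster_size_geometric()] or [cluster_size_fixed()].
#' @param cluster_span_nm window width (nm) over which one track's breaks
#'   spread; must be positive and no larger than the plasmid contour length.
#' @return An object of class `clustered_break_model`.
#' @export
clustered_break_model <- function(track_rate,
                                  cluster_size_law = cluster_size_geometric(3),
                                  cluster_span_nm = 50) {
  if (!is.numeric(track_rate) || length(track_rate) != 1L || !is.finite(track_rate) ||
      track_rate < 0) {
    stop("`track_rate` must be a single finite number >= 0", call. = FALSE)
  }
  validate_cluster_size_law(cluster_size_law)
  if (!is.numeric(cluster_span_nm) || length(cluster_span_nm) != 1L ||
      !is.finite(cluster_span_nm) || cluster_span_nm <= 0) {
    stop("`cluster_span_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(track_rate = as.numeric(track_rate),
         cluster_size_law = cluster_size_law,
         cluster_span_nm = as.numeric(cluster_span_nm)),
    class = c("clustered_break_model", "break_model")
  )
}

validate_cluster_size_law <- function(law) {
  if (!is.list(law) || is.null(law$sizes) || is.null(law$prob)) {
    stop("`cluster_size_law` must be a list with `sizes` and `prob`", call. = FALSE)
  }
  if (length(law$sizes) != length(law$prob) || length(law$sizes) == 0L) {
    stop("`sizes` and `prob` must be non-empty and of equal length", call. = FALSE)
  }
  if (any(law$sizes < 1) || any(law$sizes != round(law$sizes))) {
    stop("cluster sizes must be integers >= 1", call. = FALSE)
  }
  if (any(law$prob < 0) || abs(sum(law$prob) - 1) > 1e-8) {
    stop("cluster-size probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(law)
}

#' Cluster-size laws
#'
#' `cluster_size_geometric()` is a truncated geometric law on 1..`max_size`:
#' the success probability is `1/mean_size` (so the untruncated mean is
#' `mean_size`) and the tail beyond `max_size` is folded back by
#' renormalisation. `cluster_size_fixed()` puts all mass on one size; with
#' size 1 the clustered model reduces exactly to the uniform model at
#' `mu = track_rate`.
#'
#' @param mean_size target mean breaks per track (>= 1).
#' @param max_size truncation point of the support.
#' @param size the single deterministic cluster size.
#' @return A list with components `sizes` (integers) and `prob`.
#' @export
cluster_size_geometric <- function(mean_size, max_size = 100L) {
  if (!is.numeric(mean_size) || length(mean_size) != 1L || mean_size < 1) {
    stop("`mean_size` must be >= 1", call. = FALSE)
  }
  sizes <- seq_len(max_size)
  if (mean_size == 1) {
    prob <- c(1, rep(0, max_size - 1L))
  } else {
    p <- 1 / mean_size
    prob <- p * (1 - p)^(sizes - 1L)
    prob <- prob / sum(prob)
  }
  list(sizes = as.integer(sizes), prob = prob)
}

#' @rdname cluster_size_geometric
#' @export
cluster_size_fixed <- function(size) {
  if (!is.numeric(size) || length(size) != 1L || size < 1 || size != round(size)) {
    stop("`size` must be a single integer >= 1", call. = FALSE)
  }
  list(sizes = as.integer(size), prob = 1)
}

#' Mean of a cluster-size law
#'
#' @param law a cluster-size law (list of `sizes` and `prob`).
#' @return The expected breaks per track.
#' @export
mean_cluster_size <- function(law) {
  validate_cluster_size_law(law)
  sum(law$sizes * law$prob)
}

#' Expected breaks per plasmid under a breakage model
#'
#' @param model a `uniform_break_model` or `clustered_break_model`.
#' @return The mean number of DSBs per plasmid.
#' @export
expected_breaks <- function(model) {
  if (inherits(model, "uniform_break_model")) return(model$mu)
  if (inherits(model, "clustered_break_model")) {
    return(model$track_rate * mean_cluster_size(model$cluster_size_law))
  }
  stop("not a break model", call. = FALSE)
}

#' AFM detection / measurement emulation
#'
#' Optional measurement-layer imperfections: Gaussian contour-length noise
#' (resampled until positive, so a length can never become non-positive) and
#' a hard detection floor below which fragments are discarded. Both default
#' to off; the AFM tip radius of roughly 10 nm motivates a floor of that
#' order when one is wanted.
#'
#' @param min_detectable_nm fragments shorter than this are dropped (after
#'   noise). Non-negative; 0 disables the floor.
#' @param length_noise_sd_nm standard deviation (nm) of additive Gaussian
#'   length noise. Non-negative; 0 disables noise.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(min_detectable_nm = 0, length_noise_sd_nm = 0) {
  if (!is.numeric(min_detectable_nm) || length(min_detectable_nm) != 1L ||
      !is.finite(min_detectable_nm) || min_detectable_nm < 0) {
    stop("`min_detectable_nm` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(length_noise_sd_nm) || length(length_noise_sd_nm) != 1L ||
      !is.finite(length_noise_sd_nm) || length_noise_sd_nm < 0) {
    stop("`length_noise_sd_nm` must be a single number >= 0", call. = FALSE)
  }
  structure(
    list(min_detectable_nm = as.numeric(min_detectable_nm),
         length_noise_sd_nm = as.numeric(length_noise_sd_nm)),
    class = "detection_model"
  )
}

#' Linear dose response calibration
#'
#' Links absorbed dose to the per-plasmid break rate via `mu = alpha * dose`.
#' `dose_calibration_from_reference()` calibrates `alpha` for one of the
#' bundled reference radiations so that the 6 kGy analysis dose reproduces
#' its tabulated DSB/DNA.
#'
#' @param alpha mean DSBs per plasmid per Gy (non-negative).
#' @return An object of class `dose_calibration`.
#' @export
dose_calibration <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha)), class = "dose_calibration")
}

#' @rdname dose_calibration
#' @param radiation one of the radiation labels in [reference_table1()].
#' @param dose_Gy the dose at which the reference DSB/DNA was measured
#'   (6000 Gy for the bundled table).
#' @export
dose_calibration_from_reference <- function(radiation, dose_Gy = 6000) {
  ref <- reference_table1()
  hit <- match(tolower(radiation), tolower(ref$radiation))
  if (is.na(hit)) {
    stop(sprintf("unknown radiation '%s'; available: %s", radiation,
                 paste(ref$radiation, collapse = ", ")), call. = FALSE)
  }
  dose_calibration(ref$dsb_per_dna[hit] / dose_Gy)
}

#' Dose to break rate
#'
#' @param dose_Gy absorbed dose in Gray (non-negative).
#' @param cal a [dose_calibration()].
#' @return Mean DSBs per plasmid, `alpha * dose_Gy`.
#' @export
dose_to_break_rate <- function(dose_Gy, cal) {
  stopifnot(inherits(cal, "dose_calibration"))
  if (!is.numeric(dose_Gy) || any(!is.finite(dose_Gy)) || any(dose_Gy < 0)) {
    stop("`dose_Gy` must be finite and >= 0", call. = FALSE)
  }
  cal$alpha * dose_Gy
}

# 1 keV = 1.602176634e-16 J; the mass under 1 cm^2 x 1 um at density rho
# g/cm^3 is rho * 1e-7 kg, hence Gy per (particle/cm^2) per (keV/um):
GY_PER_FLUENCE_LET <- 1.602176634e-9

#' Dose from particle fluence and LET
#'
#' For a charged-particle beam the absorbed dose is the product of fluence
#' (fluence rate times beam-on time) and LET, divided by density:
#' `D[Gy] = 1.602176634e-9 * fluence_rate[cm^-2 s^-1] * time[s] *
#' LET[keV/um] / density[g/cm^3]`. The constant converts keV to J and the
#' cm^2 x um volume element to mass.
#'
#' @param fluence_rate particles per cm^2 per second (non-negative).
#' @param let_keV_um linear energy transfer in keV/um (non-negative).
#' @param time_s beam-on time in seconds (non-negative).
#' @param density_g_cm3 target density in g/cm^3 (positive; water = 1).
#' @return Absorbed dose in Gray.
#' @examples
#' dose_from_fluence(6.24e9, 100, 1)  # ~ 1 Gy
#' @export
dose_from_fluence <- function(fluence_rate, let_keV_um, time_s, density_g_cm3 = 1) {
  vals <- c(fluence_rate, let_keV_um, time_s)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop("fluence rate, LET and time must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(density_g_cm3) || density_g_cm3 <= 0) {
    stop("`density_g_cm3` must be positive", call. = FALSE)
  }
  GY_PER_FLUENCE_LET * fluence_rate * let_keV_um * time_s / density_g_cm3
}
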