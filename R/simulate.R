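#' Uniform break positions on a circular plasmid
#'
#' Draws `k` independent, uniformly distributed break positions on the circle
#' `[0, L)`. Uses the current R random stream; callers wanting
#' reproducibility should seed first (as [simulate_sample()] does for each
#' plasmid).
#'
#' @param k number of breaks (non-negative integer).
#' @param L circle (plasmid contour) length, positive.
#' @return Numeric vector of `k` positions in `[0, L)`.
#' @export
break_positions_uniform <- function(k, L) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0 || k != round(k)) {
    stop("`k` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  if (k == 0) return(numeric(0))
  stats::runif(k, min = 0, max = L)
}

#' Fragment lengths from break positions on a circle
#'
#' Cutting a circular molecule of length `L` at `k >= 1` positions yields
#' exactly `k` fragments (the circular spacings between sorted break points,
#' including the wrap-around gap), so fragment count equals break count. One
#' break linearises the plasmid into a single full-length fragment. With no
#' breaks the molecule stays circular and intact.
#'
#' The returned lengths are adjusted by at most a few ulps (on the largest
#' fragment) so that they sum to `L` exactly in floating point; total DNA
#' length is conserved bit-exactly.
#'
#' @param positions break positions, all in `[0, L)`.
#' @param L circle length, positive.
#' @return A list with `lengths` (numeric) and `topology` (`"linear"` per
#'   fragment, or a single `"circular"` entry of length `L` when
#'   `positions` is empty).
#' @examples
#' fragments_from_breaks(c(0, 425), 850)$lengths   # 425 425
#' fragments_from_breaks(212.5, 850)$lengths       # 850 (linearised)
#' @export
fragments_from_breaks <- function(positions, L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  if (length(positions) == 0) {
    return(list(lengths = L, topology = "circular"))
  }
  if (!is.numeric(positions) || any(!is.finite(positions)) ||
      any(positions < 0) || any(positions >= L)) {
    stop("all break positions must lie in [0, L)", call. = FALSE)
  }
  k <- length(positions)
  if (k == 1L) {
    return(list(lengths = L, topology = "linear"))
  }
  p <- sort(positions)
  lens <- c(diff(p), (L - p[k]) + p[1])
  # force bit-exact conservation: fold the floating-point residual into the
  # largest fragment (a few ulps at most)
  for (i in 1:5) {
    resid <- L - sum(lens)
    if (resid == 0) break
    j <- which.max(lens)
    lens[j] <- lens[j] + resid
  }
  list(lengths = lens, topology = rep("linear", k))
}

draw_break_count_and_positions <- function(model, L) {
  if (inherits(model, "uniform_break_model")) {
    k <- stats::rpois(1L, model$mu)
    return(break_positions_uniform(k, L))
  }
  if (inherits(model, "clustered_break_model")) {
    n_tracks <- stats::rpois(1L, model$track_rate)
    if (n_tracks == 0L) return(numeric(0))
    law <- model$cluster_size_law
    sizes <- law$sizes[sample.int(length(law$sizes), n_tracks, replace = TRUE,
                                  prob = law$prob)]
    centers <- stats::runif(n_tracks, 0, L)
    offs <- stats::runif(sum(sizes), -model$cluster_span_nm / 2,
                         model$cluster_span_nm / 2)
    pos <- rep.int(centers, sizes) + offs
    return(pos %% L)
  }
  stop("unknown break model", call. = FALSE)
}

apply_detection <- function(lengths, topology, plasmid_id, detection) {
  if (detection$length_noise_sd_nm > 0) {
    noisy <- lengths + stats::rnorm(length(lengths), 0, detection$length_noise_sd_nm)
    bad <- which(noisy <= 0)
    while (length(bad) > 0) {  # resample, never truncate to zero
      noisy[bad] <- lengths[bad] + stats::rnorm(length(bad), 0, detection$length_noise_sd_nm)
      bad <- bad[noisy[bad] <= 0]
    }
    lengths <- noisy
  }
  keep <- lengths >= detection$min_detectable_nm | topology == "circular"
  list(lengths = lengths[keep], topology = topology[keep],
       plasmid_id = plasmid_id[keep])
}

#' Simulate an AFM fragment-length sample
#'
#' Generates `n_plasmids` circular plasmids, breaks each according to
#' `model`, measures the resulting fragments (optionally with Gaussian
#' length noise and a detection floor), and returns the pooled fragment
#' table with radiation metadata — the synthetic analogue of one irradiated,
#' imaged and measured DNA aliquot.
#'
#' Randomness is fully reproducible: each plasmid runs in its own
#' deterministic sub-stream derived from `seed`, so the first `m` plasmids
#' of a size-`n` sample are identical to a size-`m` sample, and the global
#' RNG state of the caller is left untouched.
#'
#' @param model a [uniform_break_model()] or [clustered_break_model()].
#' @param plasmid a [plasmid_spec()].
#' @param n_plasmids number of plasmids in the aliquot (positive integer).
#' @param detection a [detection_model()]; default: no noise, no floor.
#' @param seed master seed (integer).
#' @param sample_id label written into every fragment record.
#' @param radiation,dose_Gy,let_keV_um metadata carried on the sample.
#' @return An object of class `sample_measurement`: list with `records`
#'   (data.frame of `sample_id`, `fragment_id`, `length_nm`, `topology`,
#'   plus the simulator ground-truth `plasmid` index), the metadata fields,
#'   `plasmid`, `model`, `detection`, `seed` and `n_plasmids`.
#' @export
simulate_sample <- function(model, plasmid, n_plasmids,
                            detection = detection_model(), seed,
                            sample_id = "sim",
                            radiation = NA_character_,
                            dose_Gy = NA_real_,
                            let_keV_um = NA_real_) {
  if (!inherits(model, "break_model")) stop("`model` must be a break model", call. = FALSE)
  if (!inherits(plasmid, "plasmid_spec")) stop("`plasmid` must be a plasmid_spec", call. = FALSE)
  if (!inherits(detection, "detection_model")) stop("`detection` must be a detection_model", call. = FALSE)
  if (!is.numeric(n_plasmids) || length(n_plasmids) != 1L || n_plasmids < 1 ||
      n_plasmids != round(n_plasmids)) {
    stop("`n_plasmids` must be a single positive integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be supplied as a single integer", call. = FALSE)
  }
  if (inherits(model, "clustered_break_model") &&
      model$cluster_span_nm > plasmid$length_nm) {
    stop("`cluster_span_nm` must not exceed the plasmid contour length", call. = FALSE)
  }
  L <- plasmid$length_nm
  n_plasmids <- as.integer(n_plasmids)

  lens_list <- vector("list", n_plasmids)
  topo_list <- vector("list", n_plasmids)
  with_preserved_rng({
    for (i in seq_len(n_plasmids)) {
      set.seed(derive_stream_seed(seed, i))
      pos <- draw_break_count_and_positions(model, L)
      fr <- fragments_from_breaks(pos, L)
      out <- apply_detection(fr$lengths, fr$topology,
                             rep.int(i, length(fr$lengths)), detection)
      lens_list[[i]] <- out$lengths
      topo_list[[i]] <- out$topology
    }
  })
  counts <- lengths(lens_list)
  records <- data.frame(
    sample_id = rep.int(sample_id, sum(counts)),
    fragment_id = seq_len(sum(counts)),
    length_nm = unlist(lens_list, use.names = FALSE),
    topology = unlist(topo_list, use.names = FALSE),
    plasmid = rep.int(seq_len(n_plasmids), counts),
    stringsAsFactors = FALSE
  )
  structure(
    list(records = records, radiation = radiation, dose_Gy = dose_Gy,
         let_keV_um = let_keV_um, plasmid = plasmid, model = model,
         detection = detection, seed = seed, n_plasmids = n_plasmids),
    class = "sample_measurement"
  )
}

#' @export
print.sample_measurement <- function(x, ...) {
  n_lin <- sum(x$records$topology == "linear")
  n_circ <- sum(x$records$topology == "circular")
  cat(sprintf(paste0(
    "<sample_measurement> '%s': %d plasmids -> %d linear fragments, ",
    "%d intact circles\n"),
    x$records$sample_id[1] %||% "?", x$n_plasmids, n_lin, n_circ))
  cat(sprintf("  radiation: %s, dose: %s Gy, LET: %s keV/um, seed: %s\n",
              x$radiation, format(x$dose_Gy), format(x$let_keV_um),
              format(x$seed)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
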