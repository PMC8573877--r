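#' Digital phantoms
#'
#' A digital phantom is an integer label map plus a region table giving each
#' region's name, ground-truth relaxation times (ms) and proton-density
#' amplitude. Label 0 is background (no signal).
#'
#' @param label_map Integer matrix; 0 = background.
#' @param regions Data frame with columns `id`, `name`, `T1`, `T2`, `A`.
#' @return An object of class `digital_phantom`.
#' @export
digital_phantom <- function(label_map, regions) {
  stopifnot(is.matrix(label_map))
  needed <- c("id", "name", "T1", "T2", "A")
  if (!all(needed %in% names(regions))) {
    stop("regions must have columns: ", paste(needed, collapse = ", "))
  }
  ids <- setdiff(unique(as.vector(label_map)), 0L)
  if (!all(ids %in% regions$id)) {
    stop("label map contains ids missing from the region table: ",
         paste(setdiff(ids, regions$id), collapse = ", "))
  }
  if (any(regions$T1 <= 0) || any(regions$T2 <= 0)) stop("region T1/T2 must be positive")
  if (any(regions$A <= 0)) stop("region amplitudes must be positive")
  area <- table(factor(as.vector(label_map), levels = regions$id))
  if (any(area < 25)) {
    warning("some regions cover fewer than 25 pixels; ROI statistics will be poor")
  }
  structure(list(label_map = label_map, regions = regions),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("Digital phantom: %d x %d grid, %d regions\n",
              nrow(x$label_map), ncol(x$label_map), nrow(x$regions)))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Logical mask of one phantom region
#'
#' @param phantom A `digital_phantom`.
#' @param name Region name as listed in `phantom$regions$name`, or a vector
#'   of names (the union mask is returned).
#' @return Logical matrix.
#' @export
region_mask <- function(phantom, name) {
  stopifnot(inherits(phantom, "digital_phantom"))
  ids <- phantom$regions$id[phantom$regions$name %in% name]
  if (length(ids) == 0L) stop("no region named: ", paste(name, collapse = ", "))
  matrix(phantom$label_map %in% ids, nrow = nrow(phantom$label_map))
}

# Reference (long-TR spin echo) T1/T2 values of the nine-vial T1MES-style
# plate, ms. Gel vials have tissue-like T2 (~40-47 ms); the three liquid
# vials have long T2 typical of blood.
t1mes_reference_values <- function() {
  data.frame(
    id = 1:9,
    name = paste0("vial", 1:9),
    T1 = c(439, 1111, 464, 572, 1361, 1527, 303, 814, 258),
    T2 = c(40.0, 44.3, 181.0, 42.5, 46.6, 234.4, 41.9, 44.8, 154.2),
    A = 1
  )
}

#' Nine-vial relaxometry phantom
#'
#' Builds a T1MES-style quality-assurance plate: nine circular vials on a
#' 3 x 3 grid, each assigned a ground-truth (T1, T2) pair from long-TR
#' spin-echo reference measurements spanning native and post-contrast
#' myocardium- and blood-like values.
#'
#' @param size Grid side length in pixels (default 128).
#' @param vial_radius Vial radius in pixels. The default of 15 px (about 700
#'   px area) keeps the sampling error of vial-median statistics small
#'   against the T2 recovery bounds: per-pixel T2 scatter in the long-T2
#'   liquid vials is large under the post-contrast protocol, so several
#'   hundred pixels per vial are needed for an estimable median.
#' @return A `digital_phantom` with regions `vial1` ... `vial9`.
#' @examples
#' ph <- make_t1mes_phantom()
#' ph$regions[1, c("T1", "T2")]  # 439 ms, 40 ms
#' @export
make_t1mes_phantom <- function(size = 128L, vial_radius = 15) {
  regions <- t1mes_reference_values()
  lab <- matrix(0L, size, size)
  centres <- expand.grid(cx = size * c(0.25, 0.5, 0.75),
                         cy = size * c(0.25, 0.5, 0.75))
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (i in 1:9) {
    inside <- (xs - centres$cx[i])^2 + (ys - centres$cy[i])^2 <= vial_radius^2
    lab[inside] <- i
  }
  digital_phantom(lab, regions)
}

# Post-contrast tissue values (ms) by clinical scenario: group means measured
# in chronic MI (n = 10) and in the elevated-T2 group (acute MI +
# myocarditis).
cardiac_tissue_values <- function(scenario) {
  if (scenario == "chronic_mi") {
    data.frame(id = 1:3, name = c("MI", "remote", "blood"),
               T1 = c(441, 668, 466), T2 = c(43.8, 42.4, 142.4), A = 1)
  } else {
    data.frame(id = 1:3, name = c("MI", "remote", "blood"),
               T1 = c(392, 608, 396), T2 = c(58.3, 41.7, 141.8), A = 1)
  }
}

#' Short-axis cardiac slice phantom with scar
#'
#' Builds an idealized mid-ventricular short-axis slice: a circular left
#' ventricular blood pool surrounded by an annular myocardium with a scar
#' sector. Chronic and acute infarct scenarios place the scar
#' subendocardially (inner half of the wall); myocarditis places it
#' subepicardially (outer half). Tissue T1/T2 default to post-contrast group
#' means: chronic MI uses MI (441, 43.8), remote (668, 42.4) and blood
#' (466, 142.4) ms; the elevated-T2 scenarios use MI (392, 58.3), remote
#' (608, 41.7) and blood (396, 141.8) ms.
#'
#' @param scenario `"chronic_mi"`, `"acute_mi"`, or `"myocarditis"`.
#' @param size Grid side length, px (default 128).
#' @param r_blood Blood-pool radius, px (default 28).
#' @param r_epi Epicardial radius, px (default 40).
#' @param scar_angle Angular extent of the scar sector, degrees (default 60).
#' @return A `digital_phantom` with regions `MI`, `remote`, `blood`; the MI,
#'   remote and blood masks are mutually exclusive.
#' @export
make_cardiac_phantom <- function(scenario = c("chronic_mi", "acute_mi", "myocarditis"),
                                 size = 128L, r_blood = 28, r_epi = 40,
                                 scar_angle = 60) {
  scenario <- match.arg(scenario)
  regions <- cardiac_tissue_values(scenario)
  centre <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  r <- sqrt((xs - centre)^2 + (ys - centre)^2)
  theta <- atan2(ys - centre, xs - centre) * 180 / pi  # (-180, 180]

  lab <- matrix(0L, size, size)
  lab[r <= r_blood] <- 3L                              # blood pool
  myo <- r > r_blood & r <= r_epi
  lab[myo] <- 2L                                       # remote myocardium
  r_mid <- (r_blood + r_epi) / 2
  in_sector <- abs(theta) <= scar_angle / 2
  scar <- if (scenario == "myocarditis") {
    myo & in_sector & r > r_mid                        # subepicardial
  } else {
    myo & in_sector & r <= r_mid                       # subendocardial
  }
  lab[scar] <- 1L
  digital_phantom(lab, regions)
}

#' Simulate a noisy mSASHA image series from a phantom
#'
#' Evaluates the noise-free forward signal model pixel-wise for every
#' protocol event and adds zero-mean Gaussian noise. The noise level is
#' referenced to the anchor image: `sd = A_ref / snr`, with `A_ref` the
#' largest region amplitude, so `snr` is the anchor-image SNR of a
#' full-amplitude region. `snr = Inf` gives the noise-free forward model.
#' Gaussian (rather than Rician) noise reflects the high-SNR regime of
#' motion-corrected averaged magnitude images; a Rician option is provided
#' for low-SNR studies.
#'
#' Frames are generated pre-registered: respiratory motion and its
#' correction are outside this simulator's scope.
#'
#' @param phantom A `digital_phantom`.
#' @param protocol A `protocol_spec`; one frame is produced per event.
#' @param snr Anchor-image signal-to-noise ratio (> 0, or `Inf`).
#' @param seed Integer seed; identical seeds reproduce the series exactly.
#' @param noise `"gaussian"` (default) or `"rician"`.
#' @return An object of class `msasha_series`: list with `frames` (array
#'   `nx x ny x n_events`), `events`, `RR`, `noise_sd`, `seed`.
#' @export
simulate_series <- function(phantom, protocol, snr = Inf, seed = 1L,
                            noise = c("gaussian", "rician")) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(protocol, "protocol_spec"))
  noise <- match.arg(noise)
  if (!(is.infinite(snr) || (is.finite(snr) && snr > 0))) {
    stop("snr must be positive (or Inf for noise-free)")
  }
  lab <- phantom$label_map
  nx <- nrow(lab); ny <- ncol(lab)
  nev <- nrow(protocol$events)

  # per-pixel tissue parameters via label lookup (background -> NA)
  idx <- match(as.vector(lab), phantom$regions$id)
  T1px <- phantom$regions$T1[idx]
  T2px <- phantom$regions$T2[idx]
  Apx <- phantom$regions$A[idx]
  delay <- event_delay(protocol$events, protocol$RR)

  frames <- array(0, dim = c(nx, ny, nev))
  for (j in seq_len(nev)) {
    s <- Apx * (1 - exp(-delay[j] / T1px))
    if (protocol$events$kind[j] == "SR+T2prep") {
      s <- s * exp(-protocol$events$TE_prep[j] / T2px)
    }
    s[is.na(s)] <- 0  # background
    frames[, , j] <- s
  }

  noise_sd <- if (is.infinite(snr)) 0 else max(phantom$regions$A) / snr
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    eps <- array(stats::rnorm(length(frames), sd = noise_sd), dim = dim(frames))
    if (noise == "rician") {
      eps2 <- array(stats::rnorm(length(frames), sd = noise_sd), dim = dim(frames))
      frames <- sqrt((frames + eps)^2 + eps2^2)
    } else {
      frames <- frames + eps
    }
  }

  structure(
    list(frames = frames, events = protocol$events, RR = protocol$RR,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "msasha_series"
  )
}

#' @export
print.msasha_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("mSASHA series: %d frames of %d x %d px, noise sd = %g, seed = %d\n",
              d[3], d[1], d[2], x$noise_sd, x$seed))
  invisible(x)
}
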