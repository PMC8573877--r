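#' Tissue reference constants for calculated PSIR LGE
#'
#' Holds the nulling and suppression constants used by the linear PSIR
#' formulation: normal-myocardium rates (`R1m`, `R2m`), blood-pool rates
#' (`R1b`, `R2b`), the target blood signal level `LGEb`, and the derived
#' mixing weight `a_DB` computed by [compute_a_db()]. All rates are in Hz.
#'
#' `LGEb` sets how deeply the blood pool is suppressed in the dark-blood
#' image: the calculated DB signal of blood lands exactly at `LGEb`. The
#' default of -0.5 Hz places blood below the nulled myocardium.
#'
#' @param R1m,R2m Normal-myocardium longitudinal/transverse rates, Hz.
#' @param R1b,R2b Blood-pool rates, Hz. `R2b` must differ from `R2m` and
#'   `R1b` must differ from `LGEb` (both appear in denominators of the
#'   analytic `a_DB` solution).
#' @param LGEb Target blood signal level, Hz. Default -0.5.
#' @return An object of class `tissue_reference` with the five constants and
#'   `a_DB`.
#' @examples
#' ref <- tissue_reference(R1m = 1000 / 668, R2m = 1000 / 42.4,
#'                         R1b = 1000 / 466, R2b = 1000 / 142.4)
#' ref$a_DB  # about 0.618
#' @export
tissue_reference <- function(R1m, R2m, R1b, R2b, LGEb = -0.5) {
  for (v in c(R1m = R1m, R2m = R2m, R1b = R1b, R2b = R2b)) {
    if (!is.finite(v) || v <= 0) stop("reference rates must be positive and finite")
  }
  if (!is.finite(LGEb)) stop("LGEb must be finite")
  ref <- structure(list(R1m = R1m, R2m = R2m, R1b = R1b, R2b = R2b,
                        LGEb = LGEb, a_DB = NA_real_),
                   class = "tissue_reference")
  ref$a_DB <- compute_a_db(ref)
  ref
}

#' Reference constants from relaxation times
#'
#' Convenience wrapper building a [tissue_reference()] from myocardial and
#' blood T1/T2 in ms.
#'
#' @param myocardium,blood [tissue_relaxation()] objects (or lists with
#'   `T1`, `T2` in ms).
#' @param LGEb Target blood signal level, Hz.
#' @return A `tissue_reference`.
#' @export
tissue_reference_from_times <- function(myocardium, blood, LGEb = -0.5) {
  tissue_reference(R1m = 1000 / myocardium$T1, R2m = 1000 / myocardium$T2,
                   R1b = 1000 / blood$T1, R2b = 1000 / blood$T2, LGEb = LGEb)
}

#' @export
print.tissue_reference <- function(x, ...) {
  cat(sprintf(paste0("PSIR tissue reference (Hz): R1m = %.4g, R2m = %.4g, ",
                     "R1b = %.4g, R2b = %.4g\n  LGEb = %.4g -> a_DB = %.4g\n"),
              x$R1m, x$R2m, x$R1b, x$R2b, x$LGEb, x$a_DB))
  invisible(x)
}

#' Analytic blood-suppression weight for dark-blood PSIR
#'
#' Solves for the weight `a_DB` that makes the dark-blood PSIR expression
#' null the normal myocardium while fixing the blood-pool signal at `LGEb`:
#' `a_DB = (R1m * R2m / (R1b - LGEb) - R2m) / (R2b - R2m)`.
#' It is obtained by setting the DB signal at the blood operating point
#' `(R1b, R2b)` equal to `LGEb` and solving.
#'
#' @param ref A `tissue_reference` (the `LGEb` stored in it is used).
#' @return Dimensionless weight.
#' @export
compute_a_db <- function(ref) {
  stopifnot(inherits(ref, "tissue_reference"))
  if (abs(ref$R2b - ref$R2m) < 1e-12) {
    stop("a_DB is undefined when blood and myocardial R2 coincide (R2b = R2m)")
  }
  if (abs(ref$R1b - ref$LGEb) < 1e-12) {
    stop("a_DB is undefined when LGEb equals the blood R1 (R1b)")
  }
  (ref$R1m * ref$R2m / (ref$R1b - ref$LGEb) - ref$R2m) / (ref$R2b - ref$R2m)
}

#' Calculated bright-blood PSIR LGE image
#'
#' Computes the linear-in-concentration bright-blood PSIR signal
#' `R1 - R1m` per pixel. Normal myocardium (R1 = R1m) is nulled exactly;
#' shorter-T1 tissue such as enhancing scar is positive; and because R1 is
#' affine in gadolinium concentration the signal itself is proportional to
#' concentration, unlike the exponential inversion-recovery signal.
#'
#' @param R1_map Matrix of longitudinal rates, Hz (`NA` where the fit did
#'   not converge; propagated).
#' @param ref A `tissue_reference` supplying `R1m`.
#' @return An object of class `psir_image` with fields `values` (Hz),
#'   `kind = "BB"`, `reference`.
#' @export
calc_bb_psir <- function(R1_map, ref) {
  stopifnot(is.numeric(R1_map), inherits(ref, "tissue_reference"))
  structure(list(values = R1_map - ref$R1m, kind = "BB", reference = ref),
            class = "psir_image")
}

#' Calculated dark-blood PSIR LGE image
#'
#' Computes the dark-blood PSIR signal
#' `R1 - R1m / (a_DB * R2 / R2m + (1 - a_DB))` per pixel, with `a_DB` from
#' [compute_a_db()]. Where R2 equals the myocardial reference the expression
#' collapses to the bright-blood signal, so normal myocardium is still
#' nulled; at the blood operating point `(R1b, R2b)` the signal equals
#' `LGEb` by construction.
#'
#' Pixels where the denominator is non-positive (possible for extreme R2
#' when `a_DB > 1` or `< 0`) are returned as `NaN`; their count is reported
#' via a message.
#'
#' @param R1_map,R2_map Co-registered rate maps, Hz.
#' @param ref A `tissue_reference`.
#' @return A `psir_image` with `kind = "DB"`.
#' @export
calc_db_psir <- function(R1_map, R2_map, ref) {
  stopifnot(is.numeric(R1_map), is.numeric(R2_map),
            inherits(ref, "tissue_reference"))
  if (length(R1_map) != length(R2_map)) {
    stop("R1 and R2 maps must be co-registered (same dimensions)")
  }
  denom <- ref$a_DB * R2_map / ref$R2m + (1 - ref$a_DB)
  bad <- is.finite(denom) & denom <= 0
  if (any(bad)) {
    message(sum(bad), " pixel(s) with non-positive DB denominator set to NaN")
    denom[bad] <- NaN
  }
  structure(list(values = R1_map - ref$R1m / denom, kind = "DB", reference = ref),
            class = "psir_image")
}

#' @export
print.psir_image <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("Calculated %s PSIR image: %d finite px, range [%.3g, %.3g] Hz\n",
              x$kind, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Normal-tissue values as the median over a mask
#'
#' Estimates the normal myocardial (T1m, T2m) as the per-map median over a
#' segmentation mask, using converged pixels only. The median is preferred
#' to the mean because it is robust to a regional abnormality (scar) inside
#' the segmented myocardium; the PSIR formulation itself tolerates moderate
#' error in the assumed normal value, which can be compensated by
#' window-leveling.
#'
#' @param maps A `relaxation_maps` object.
#' @param mask Non-empty logical matrix on the maps' grid.
#' @return Named numeric vector `c(T1m = ..., T2m = ...)`, ms.
#' @export
estimate_normal_values <- function(maps, mask) {
  stopifnot(inherits(maps, "relaxation_maps"), is.logical(mask))
  if (!all(dim(mask) == dim(maps$T1))) stop("mask does not match the map grid")
  sel <- mask & maps$converged
  if (!any(sel)) stop("mask selects no converged pixels")
  c(T1m = stats::median(maps$T1[sel]), T2m = stats::median(maps$T2[sel]))
}

#' Reference constants estimated from fitted maps and masks
#'
#' Symmetric estimation of the myocardial and blood reference points: the
#' median T1 and T2 over each mask (converged pixels only), converted to
#' rates.
#'
#' @param maps A `relaxation_maps`.
#' @param myo_mask,blood_mask Logical masks for myocardium and blood pool.
#' @param LGEb Target blood signal level, Hz.
#' @return A `tissue_reference`.
#' @export
tissue_reference_from_maps <- function(maps, myo_mask, blood_mask, LGEb = -0.5) {
  m <- estimate_normal_values(maps, myo_mask)
  b <- estimate_normal_values(maps, blood_mask)
  tissue_reference(R1m = 1000 / m[["T1m"]], R2m = 1000 / m[["T2m"]],
                   R1b = 1000 / b[["T1m"]], R2b = 1000 / b[["T2m"]], LGEb = LGEb)
}

#' Dark-blood images across a sweep of blood-suppression levels
#'
#' Recomputes the dark-blood PSIR image for each requested `LGEb`,
#' re-deriving `a_DB` each time. Sweeping `LGEb` from positive (bright
#' blood) through zero (grey blood) to negative values deepens the blood
#' suppression; the blood-region signal equals each `LGEb` by construction.
#'
#' @param R1_map,R2_map Co-registered rate maps, Hz.
#' @param ref A `tissue_reference`; its `LGEb` is overridden per sweep value.
#' @param lgeb_values Numeric vector of blood signal levels, Hz. None may
#'   equal `ref$R1b`.
#' @return Named list of `psir_image`s, one per `LGEb`.
#' @export
lgeb_sweep <- function(R1_map, R2_map, ref, lgeb_values) {
  stopifnot(inherits(ref, "tissue_reference"))
  out <- lapply(lgeb_values, function(l) {
    r <- tissue_reference(ref$R1m, ref$R2m, ref$R1b, ref$R2b, LGEb = l)
    calc_db_psir(R1_map, R2_map, r)
  })
  names(out) <- sprintf("LGEb=%g", lgeb_values)
  out
}

#' Attenuation of the dark-blood signal by myocardial edema
#'
#' Edema elevates T2; in the dark-blood formulation an elevated R2 deviation
#' from the myocardial reference shrinks the computed signal, attenuating
#' enhancing edematous tissue relative to its bright-blood value. For each
#' (T1, T2) pair on the supplied grid this returns the ratio
#' `DB PSIR(T1, T2) / BB PSIR(T1)` — the factor by which T2 elevation
#' reduces the dark-blood signal relative to its T2-neutral value. When the
#' edematous T1 equals the remote T1 the bright-blood signal is zero and the
#' ratio is undefined (`NaN`).
#'
#' @param edema_T1_grid,edema_T2_grid Positive grids of edematous-tissue T1
#'   and T2, ms.
#' @param remote [tissue_relaxation()] of remote (normal) myocardium.
#' @param blood [tissue_relaxation()] of the blood pool.
#' @param LGEb Blood signal level, Hz (default -0.5; attenuation is milder
#'   with less suppression).
#' @return Matrix of attenuation factors, rows indexed by T1, columns by T2,
#'   with dimnames giving the grid values.
#' @export
db_attenuation_curve <- function(edema_T1_grid, edema_T2_grid, remote, blood,
                                 LGEb = -0.5) {
  if (any(edema_T1_grid <= 0) || any(edema_T2_grid <= 0)) {
    stop("T1/T2 grids must be positive")
  }
  ref <- tissue_reference_from_times(remote, blood, LGEb = LGEb)
  att <- matrix(NA_real_, length(edema_T1_grid), length(edema_T2_grid),
                dimnames = list(T1 = edema_T1_grid, T2 = edema_T2_grid))
  for (i in seq_along(edema_T1_grid)) {
    r1 <- 1000 / edema_T1_grid[i]
    bb <- r1 - ref$R1m
    r2 <- 1000 / edema_T2_grid
    db <- r1 - ref$R1m / (ref$a_DB * r2 / ref$R2m + (1 - ref$a_DB))
    att[i, ] <- if (abs(bb) < 1e-12) NaN else db / bb
  }
  att
}
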