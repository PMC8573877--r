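#' Tissue relaxation parameters
#'
#' Bundles the longitudinal and transverse relaxation times of a tissue
#' compartment together with the derived relaxation rates. Times are stored in
#' milliseconds; rates in Hz, so `R1 = 1000 / T1` and `R2 = 1000 / T2`.
#'
#' @param T1 Longitudinal relaxation time in ms. Must be positive.
#' @param T2 Transverse relaxation time in ms. Must be positive. May be `NA`
#'   for applications that only need T1 (e.g. bright-blood PSIR).
#'
#' @return An object of class `tissue_relaxation` with fields `T1`, `T2`,
#'   `R1`, `R2`.
#' @examples
#' remote <- tissue_relaxation(668, 42.4)
#' remote$R1  # about 1.50 Hz
#' @export
tissue_relaxation <- function(T1, T2 = NA_real_) {
  stopifnot(is.numeric(T1), length(T1) == 1L)
  if (!is.finite(T1) || T1 <= 0) {
    stop("T1 must be a positive, finite time in ms (got ", T1, ")")
  }
  if (!is.na(T2) && (!is.finite(T2) || T2 <= 0)) {
    stop("T2 must be a positive, finite time in ms (got ", T2, ")")
  }
  structure(
    list(T1 = T1, T2 = T2, R1 = 1000 / T1, R2 = 1000 / T2),
    class = "tissue_relaxation"
  )
}

#' @export
print.tissue_relaxation <- function(x, ...) {
  cat(sprintf("Tissue relaxation: T1 = %.4g ms (R1 = %.4g Hz)", x$T1, x$R1))
  if (!is.na(x$T2)) {
    cat(sprintf(", T2 = %.4g ms (R2 = %.4g Hz)", x$T2, x$R2))
  }
  cat("\n")
  invisible(x)
}

#' Convert between relaxation times and rates
#'
#' `r1_from_t1()` converts a relaxation time in ms to a rate in Hz
#' (`R = 1000 / T`); `t1_from_r1()` is its exact inverse. The same reciprocal
#' relation holds for T2/R2, so these functions serve both axes.
#'
#' @param T1 Relaxation time(s), ms. All values must be positive.
#' @param R1 Relaxation rate(s), Hz. All values must be positive.
#' @return Numeric vector of rates in Hz (or times in ms for the inverse).
#' @examples
#' r1_from_t1(c(441, 668, 466))  # approx 2.27, 1.50, 2.15 Hz
#' t1_from_r1(r1_from_t1(668))   # 668 exactly
#' @export
r1_from_t1 <- function(T1) {
  if (any(!is.finite(T1) | T1 <= 0)) stop("relaxation times must be positive and finite")
  1000 / T1
}

#' @rdname r1_from_t1
#' @export
t1_from_r1 <- function(R1) {
  if (any(!is.finite(R1) | R1 <= 0)) stop("relaxation rates must be positive and finite")
  1000 / R1
}

#' Gadolinium concentration from the change in transverse relaxation rate
#'
#' In the fast-exchange regime the transverse rate is linear in contrast
#' concentration, `R2 = R2_0 + r2 * [Gd]`, so the concentration follows from
#' the native and post-contrast T2:
#' `[Gd] = (1000 / T2_post - 1000 / T2_native) / r2`.
#'
#' @param T2_native Native (pre-contrast) T2, ms.
#' @param T2_post Post-contrast T2, ms. Must not exceed `T2_native`: contrast
#'   can only shorten T2.
#' @param r2 Transverse relaxivity of the agent, s^-1 mmol^-1 L. Default 5.85,
#'   typical for gadoterate meglumine at 1.5 T.
#' @return Concentration in mmol/L.
#' @examples
#' gd_concentration_from_r2(250, 142)  # about 0.52 mmol/L
#' @export
gd_concentration_from_r2 <- function(T2_native, T2_post, r2 = 5.85) {
  stopifnot(is.numeric(T2_native), is.numeric(T2_post))
  if (any(T2_native <= 0) || any(T2_post <= 0)) stop("T2 values must be positive")
  if (!is.finite(r2) || r2 <= 0) stop("relaxivity r2 must be positive")
  if (any(T2_post > T2_native)) {
    stop("T2_post exceeds T2_native: implied concentration would be negative. ",
         "Check that the arguments are not swapped.")
  }
  (1000 / T2_post - 1000 / T2_native) / r2
}

#' @description `t2_post_from_concentration()` is the forward relaxivity
#'   model: given a native T2 and a concentration it returns the shortened
#'   post-contrast T2, the exact inverse of `gd_concentration_from_r2()`.
#' @param concentration Contrast concentration, mmol/L (non-negative).
#' @rdname gd_concentration_from_r2
#' @export
t2_post_from_concentration <- function(T2_native, concentration, r2 = 5.85) {
  if (any(T2_native <= 0)) stop("T2_native must be positive")
  if (any(concentration < 0)) stop("concentration must be non-negative")
  1000 / (1000 / T2_native + r2 * concentration)
}
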