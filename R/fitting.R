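#' Joint three-parameter fit of one pixel's mSASHA signals
#'
#' Estimates amplitude, T1 and T2 simultaneously by nonlinear least squares
#' against the saturation-recovery forward model: anchors constrain the
#' amplitude, plain SR frames constrain T1, and T2-prepared frames constrain
#' T2. Joint fitting decouples the estimates: T1 no longer depends on T2 nor
#' T2 on T1. All three preparation kinds must be present or the parameters
#' are not identifiable.
#'
#' Magnitude data are fitted as real-valued: saturation-recovered signal is
#' non-negative, so no polarity restoration is needed (an advantage of
#' saturation over inversion preparations).
#'
#' Optimization uses Levenberg-Marquardt (\pkg{minpack.lm}) with box bounds
#' T1 in \[50, 5000\] ms, T2 in \[5, 1000\] ms, A > 0. Starting values come
#' from closed-form inversions of single frames: `A0` is the strongest
#' anchor signal, `T10 = -TS / log(1 - S_SR / A0)` clipped to \[100, 3000\]
#' ms, and `T20 = -TE / log(S_T2prep / S_SR)` clipped to \[10, 500\] ms.
#' Fits that end on a bound, fail to converge within 200 iterations, or
#' receive degenerate data are returned with `converged = FALSE` rather than
#' raising an error.
#'
#' @param signals Numeric vector of measured magnitudes, one per protocol
#'   event, in event order.
#' @param protocol The `protocol_spec` that produced the signals. Must
#'   contain at least one event of each preparation kind.
#' @return A list with `A`, `T1`, `T2` (ms), `residual` (root-mean-square
#'   misfit) and `converged` (logical).
#' @examples
#' p <- default_msasha_protocol()
#' y <- psirsynth:::protocol_signal(p, A = 1, T1 = 668, T2 = 42.4)
#' fit_pixel(y, p)$T1  # 668 to within numerical tolerance
#' @export
fit_pixel <- function(signals, protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  ev <- protocol$events
  if (length(signals) != nrow(ev)) {
    stop("got ", length(signals), " signals for ", nrow(ev), " protocol events")
  }
  kinds <- unique(ev$kind)
  if (!all(c("anchor", "SR", "SR+T2prep") %in% kinds)) {
    stop("joint (A, T1, T2) fitting needs anchor, SR and SR+T2prep events; ",
         "protocol has only: ", paste(kinds, collapse = ", "))
  }
  bad_fit <- list(A = NA_real_, T1 = NA_real_, T2 = NA_real_,
                  residual = NA_real_, converged = FALSE)
  if (any(!is.finite(signals))) return(bad_fit)

  delay <- event_delay(ev, protocol$RR)
  is_t2p <- ev$kind == "SR+T2prep"
  te <- ifelse(is_t2p, ev$TE_prep, 0)

  start <- fit_start_values(signals, ev, te)
  if (is.null(start)) return(bad_fit)

  lower <- c(A = 1e-8, T1 = 50, T2 = 5)
  upper <- c(A = Inf, T1 = 5000, T2 = 1000)
  resid_fn <- function(par) {
    par["A"] * (1 - exp(-delay / par["T1"])) * exp(-te / par["T2"]) - signals
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(bad_fit)

  par <- fit$par
  on_bound <- par["T1"] <= lower["T1"] * (1 + 1e-9) ||
    par["T1"] >= upper["T1"] * (1 - 1e-9) ||
    par["T2"] <= lower["T2"] * (1 + 1e-9) ||
    par["T2"] >= upper["T2"] * (1 - 1e-9)
  converged <- fit$info %in% 1:4 && !on_bound && all(is.finite(par))
  list(A = unname(par["A"]), T1 = unname(par["T1"]), T2 = unname(par["T2"]),
       residual = sqrt(mean(fit$fvec^2)), converged = converged)
}

# Closed-form starting values; NULL when the data are degenerate (e.g. all
# zero or negative anchors).
fit_start_values <- function(signals, ev, te) {
  a0 <- max(signals[ev$kind == "anchor"])
  if (!is.finite(a0) || a0 <= 0) return(NULL)
  s_sr <- stats::median(signals[ev$kind == "SR"])
  s_t2 <- stats::median(signals[ev$kind == "SR+T2prep"])
  ts <- stats::median(ev$TS[ev$kind == "SR"])
  te1 <- stats::median(te[ev$kind == "SR+T2prep"])

  t10 <- if (is.finite(s_sr) && s_sr > 0 && s_sr < a0) {
    -ts / log(1 - s_sr / a0)
  } else 1000
  t20 <- if (is.finite(s_t2) && s_t2 > 0 && is.finite(s_sr) && s_sr > s_t2) {
    -te1 / log(s_t2 / s_sr)
  } else 50
  c(A = a0, T1 = min(max(t10, 100), 3000), T2 = min(max(t20, 10), 500))
}

#' Pixel-wise joint T1/T2 mapping of an image series
#'
#' Applies [fit_pixel()] to every pixel inside `mask` (every pixel when no
#' mask is given) and assembles amplitude, T1, T2 and residual maps on the
#' series' grid. Pixels outside the mask are `NA` and marked unconverged.
#' The fit is deterministic: identical series give identical maps.
#'
#' @param series An `msasha_series` (from [simulate_series()] or
#'   [read_series()]).
#' @param protocol Optional `protocol_spec`; defaults to the event table and
#'   RR carried by the series.
#' @param mask Optional logical matrix selecting pixels to fit.
#' @return An object of class `relaxation_maps`: list of matrices `A`, `T1`,
#'   `T2` (ms), `residual`, and logical `converged`.
#' @export
fit_maps <- function(series, protocol = NULL, mask = NULL) {
  stopifnot(inherits(series, "msasha_series"))
  if (is.null(protocol)) {
    protocol <- protocol_spec(series$events, RR = series$RR, name = "from-series")
  }
  d <- dim(series$frames)
  if (nrow(protocol$events) != d[3]) {
    stop("protocol has ", nrow(protocol$events), " events but series has ",
         d[3], " frames")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, d[1], d[2])
  } else if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("mask must be a logical matrix matching the series grid")
  }

  empty <- matrix(NA_real_, d[1], d[2])
  out <- list(A = empty, T1 = empty, T2 = empty, residual = empty,
              converged = matrix(FALSE, d[1], d[2]))
  sig <- matrix(series$frames, nrow = d[1] * d[2], ncol = d[3])
  px <- which(mask)

  # identical signal vectors (noise-free phantoms) are fitted once
  keys <- apply(sig[px, , drop = FALSE], 1L, paste, collapse = "\r")
  first <- !duplicated(keys)
  cache <- new.env(parent = emptyenv())
  for (i in px[first]) {
    assign(keys[match(i, px)], fit_pixel(sig[i, ], protocol), envir = cache)
  }
  for (k in seq_along(px)) {
    f <- get(keys[k], envir = cache)
    i <- px[k]
    out$A[i] <- f$A; out$T1[i] <- f$T1; out$T2[i] <- f$T2
    out$residual[i] <- f$residual; out$converged[i] <- f$converged
  }
  structure(out, class = "relaxation_maps")
}

#' @export
print.relaxation_maps <- function(x, ...) {
  n <- sum(!is.na(x$T1))
  cat(sprintf("Relaxation maps: %d x %d px, %d fitted (%d converged)\n",
              nrow(x$T1), ncol(x$T1), n, sum(x$converged)))
  if (n > 0) {
    ok <- x$converged
    cat(sprintf("  T1 median %.1f ms, T2 median %.1f ms over converged pixels\n",
                stats::median(x$T1[ok]), stats::median(x$T2[ok])))
  }
  invisible(x)
}
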