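#' PSIR signal of an inversion-recovery LGE sequence
#'
#' Closed-form phase-sensitive signal of the standard bright-blood IR LGE
#' acquisition, `1 - 2 * exp(-TI / T1)`, assuming perfect inversion and full
#' recovery between preparations. The signal is zero at the null point
#' `TI = T1 * log(2)`, negative before it and positive after it.
#'
#' @param TI Inversion time, ms (>= 0). Vectorized.
#' @param T1 Longitudinal relaxation time, ms, or a [tissue_relaxation()]
#'   object. Vectorized when numeric.
#' @return Dimensionless signed signal in `[-1, 1]`.
#' @examples
#' ir_psir_signal(668 * log(2), 668)  # 0: normal myocardium nulled
#' ir_psir_signal(0, 668)             # -1: full inversion
#' @export
ir_psir_signal <- function(TI, T1) {
  T1 <- as_t1(T1)
  if (any(TI < 0)) stop("TI must be non-negative")
  1 - 2 * exp(-TI / T1)
}

#' PSIR signal of an inversion-recovery sequence with T2 preparation
#'
#' Signed signal of the dark-blood IR-T2 sequence, in which a T2 preparation
#' with echo time `TE` is inserted between two inversion delays `TD1` and
#' `TD2`. The T2 weighting shifts the null time of long-T2 species (blood)
#' relative to myocardium, which is what suppresses the blood pool:
#' `1 - (1 - (1 - 2 exp(-TD1/T1)) exp(-TE/T2)) exp(-TD2/T1)`.
#'
#' With `TE = 0` this reduces exactly to [ir_psir_signal()] at
#' `TI = TD1 + TD2`.
#'
#' @param TD1,TD2 Inversion delays before and after the T2 preparation, ms.
#' @param TE T2-preparation echo time, ms.
#' @param T1,T2 Tissue relaxation times, ms, or a single [tissue_relaxation()]
#'   passed as `T1`.
#' @return Dimensionless signed signal.
#' @export
ir_t2_psir_signal <- function(TD1, TD2, TE, T1, T2 = NULL) {
  if (inherits(T1, "tissue_relaxation")) {
    T2 <- T1$T2
    T1 <- T1$T1
  }
  if (any(!is.finite(T1) | T1 <= 0)) stop("T1 must be positive and finite")
  if (any(!is.finite(T2) | T2 <= 0)) stop("T2 must be positive and finite")
  if (any(TD1 < 0) || any(TD2 < 0) || any(TE < 0)) stop("timings must be non-negative")
  mz_after_prep <- (1 - 2 * exp(-TD1 / T1)) * exp(-TE / T2)
  1 - (1 - mz_after_prep) * exp(-TD2 / T1)
}

#' mSASHA single-shot image signal for one preparation type
#'
#' Magnitude signal of one frame of the multi-parametric SASHA acquisition.
#' Three preparation kinds are modelled, all starting from saturated
#' (zeroed) magnetization:
#' \describe{
#'   \item{`"anchor"`}{long recovery after saturation:
#'     `A * (1 - exp(-recovery_duration / T1))`, where the recovery duration
#'     is the idle heartbeats plus the saturation delay (3 RR + TS in the
#'     default protocol), approximating the equilibrium amplitude.}
#'   \item{`"SR"`}{saturation recovery with delay `TS`:
#'     `A * (1 - exp(-TS / T1))`.}
#'   \item{`"SR+T2prep"`}{saturation recovery followed by a T2 preparation
#'     immediately before readout: `A * (1 - exp(-TS / T1)) * exp(-TE_prep / T2)`.}
#' }
#' Saturation makes each frame independent of its predecessors, so no signal
#' depends on acquisition order. Perfect saturation efficiency and an ideal
#' (readout-free) recovery are assumed.
#'
#' @param prep_kind One of `"anchor"`, `"SR"`, `"SR+T2prep"`.
#' @param TS Saturation-recovery delay, ms (>= 0).
#' @param TE_prep T2-preparation echo time, ms; required (>= 0) for
#'   `"SR+T2prep"`, ignored otherwise.
#' @param recovery_duration Total recovery after saturation for anchor
#'   frames, ms; ignored for the other kinds.
#' @param A Equilibrium amplitude (proton density), > 0.
#' @param T1,T2 Tissue relaxation times, ms (vectorized), or a
#'   [tissue_relaxation()] passed as `T1`.
#' @return Signal in `[0, A]`.
#' @examples
#' msasha_signal("SR", TS = 300, A = 1, T1 = 668)  # 1 - exp(-300/668)
#' @export
msasha_signal <- function(prep_kind, TS = NA_real_, TE_prep = NA_real_,
                          recovery_duration = NA_real_, A = 1, T1, T2 = NULL) {
  if (inherits(T1, "tissue_relaxation")) {
    T2 <- T1$T2
    T1 <- T1$T1
  }
  prep_kind <- match.arg(prep_kind, c("anchor", "SR", "SR+T2prep"))
  if (any(!is.finite(T1) | T1 <= 0)) stop("T1 must be positive and finite")
  if (any(A <= 0)) stop("amplitude A must be positive")
  switch(prep_kind,
    anchor = {
      if (any(!is.finite(recovery_duration) | recovery_duration < 0)) {
        stop("anchor frames need a non-negative recovery_duration")
      }
      A * (1 - exp(-recovery_duration / T1))
    },
    SR = {
      if (any(!is.finite(TS) | TS < 0)) stop("TS must be non-negative")
      A * (1 - exp(-TS / T1))
    },
    `SR+T2prep` = {
      if (any(!is.finite(TS) | TS < 0)) stop("TS must be non-negative")
      if (any(!is.finite(TE_prep) | TE_prep < 0)) stop("TE_prep must be non-negative")
      if (is.null(T2) || any(!is.finite(T2) | T2 <= 0)) stop("T2 must be positive and finite")
      A * (1 - exp(-TS / T1)) * exp(-TE_prep / T2)
    }
  )
}

# Accept either a bare numeric T1 or a tissue_relaxation object.
as_t1 <- function(T1) {
  if (inherits(T1, "tissue_relaxation")) T1 <- T1$T1
  if (any(!is.finite(T1) | T1 <= 0)) stop("T1 must be positive and finite")
  T1
}
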