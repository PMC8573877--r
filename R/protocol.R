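#' Preparation events and acquisition protocols
#'
#' A protocol is an ordered table of preparation events, each producing one
#' single-shot image. An event has a kind (`"anchor"`, `"SR"`, or
#' `"SR+T2prep"`), a saturation delay `TS` (ms), an optional T2-preparation
#' echo time `TE_prep` (ms), and a count of idle recovery heartbeats that
#' precede its acquisition beat.
#'
#' @param kind Preparation kind, one of `"anchor"`, `"SR"`, `"SR+T2prep"`.
#' @param TS Saturation delay, ms.
#' @param TE_prep T2-preparation echo time, ms (`NA` unless `"SR+T2prep"`).
#' @param recovery_beats Idle heartbeats before the acquisition beat.
#'   Defaults per kind: anchor 3, SR 0, SR+T2prep 1.
#' @return A one-row data frame describing the event.
#' @export
preparation_event <- function(kind, TS = 300, TE_prep = NA_real_,
                              recovery_beats = NULL) {
  kind <- match.arg(kind, c("anchor", "SR", "SR+T2prep"))
  if (is.null(recovery_beats)) {
    recovery_beats <- switch(kind, anchor = 3L, SR = 0L, `SR+T2prep` = 1L)
  }
  if (TS < 0) stop("TS must be non-negative")
  if (recovery_beats < 0) stop("recovery_beats must be non-negative")
  if (kind == "SR+T2prep" && (is.na(TE_prep) || TE_prep < 0)) {
    stop("SR+T2prep events need a non-negative TE_prep")
  }
  data.frame(kind = kind, TS = TS, TE_prep = TE_prep,
             recovery_beats = as.integer(recovery_beats))
}

#' Construct an acquisition protocol
#'
#' @param events Data frame of preparation events, e.g. built by rbind-ing
#'   [preparation_event()] rows. Must be non-empty.
#' @param RR Heartbeat (R-R) interval, ms. Default 1000 ms (60 bpm); the
#'   schedule is parameterized rather than assuming a heart rate.
#' @param name Protocol label.
#' @return An object of class `protocol_spec`.
#' @seealso [default_msasha_protocol()], [heartbeat_cost()],
#'   [acquisition_times()]
#' @export
protocol_spec <- function(events, RR = 1000, name = "custom") {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    stop("a protocol needs at least one preparation event")
  }
  needed <- c("kind", "TS", "TE_prep", "recovery_beats")
  if (!all(needed %in% names(events))) {
    stop("events must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(events$kind %in% c("anchor", "SR", "SR+T2prep"))) {
    stop("unknown preparation kind in events")
  }
  if (!is.finite(RR) || RR <= 0) stop("RR must be a positive interval in ms")
  if (any(events$recovery_beats < 0)) stop("recovery_beats must be non-negative")
  rownames(events) <- NULL
  structure(list(name = name, RR = RR, events = events), class = "protocol_spec")
}

#' The default post-contrast mSASHA protocol
#'
#' Thirty single-shot images over 45 heartbeats: 3 anchor images with 3
#' recovery beats each (recovery duration 3 RR + TS), 6 T2-prepared
#' saturation-recovery images with TE = 55 ms and 1 recovery beat each, and
#' 21 plain saturation-recovery images with TS = 300 ms and no recovery
#' beats. Anchors are scheduled first, then the T2-prepped frames, then the
#' SR frames; because every frame starts from saturation the signal model is
#' independent of this ordering.
#'
#' @param TS Saturation delay, ms (default 300, the post-contrast setting).
#' @param TE_prep T2-preparation echo time, ms (default 55).
#' @param RR Heartbeat interval, ms (default 1000).
#' @param n_anchor,n_t2prep,n_sr Frame counts per preparation kind
#'   (defaults 3, 6, 21).
#' @return A `protocol_spec`.
#' @examples
#' p <- default_msasha_protocol()
#' nrow(p$events)     # 30 images
#' heartbeat_cost(p)  # 45 heartbeats
#' @export
default_msasha_protocol <- function(TS = 300, TE_prep = 55, RR = 1000,
                                    n_anchor = 3L, n_t2prep = 6L, n_sr = 21L) {
  ev <- rbind(
    do.call(rbind, replicate(n_anchor, preparation_event("anchor", TS = TS),
                             simplify = FALSE)),
    do.call(rbind, replicate(n_t2prep,
                             preparation_event("SR+T2prep", TS = TS, TE_prep = TE_prep),
                             simplify = FALSE)),
    do.call(rbind, replicate(n_sr, preparation_event("SR", TS = TS),
                             simplify = FALSE))
  )
  protocol_spec(ev, RR = RR, name = "msasha-default")
}

#' Heartbeat cost of a protocol
#'
#' Each event occupies its recovery beats plus one acquisition beat; the cost
#' is the sum over events. The default mSASHA protocol costs
#' 3*(3+1) + 6*(1+1) + 21*(0+1) = 45 beats.
#'
#' @param p A `protocol_spec`.
#' @return Integer number of heartbeats.
#' @export
heartbeat_cost <- function(p) {
  stopifnot(inherits(p, "protocol_spec"))
  sum(p$events$recovery_beats + 1L)
}

#' Absolute acquisition start times of a protocol's events
#'
#' Lays the events out on the heartbeat grid: each event is acquired on the
#' beat following its recovery beats. Times are in ms from the start of the
#' scan; the last acquisition starts at `(heartbeat_cost(p) - 1) * RR`.
#'
#' @param p A `protocol_spec` with `RR > 0`.
#' @return Strictly increasing numeric vector, one time per event.
#' @export
acquisition_times <- function(p) {
  stopifnot(inherits(p, "protocol_spec"))
  beat <- cumsum(p$events$recovery_beats + 1L) - 1L
  beat * p$RR
}

#' @export
print.protocol_spec <- function(x, ...) {
  counts <- table(x$events$kind)
  cat(sprintf("Protocol '%s': %d images over %d heartbeats (RR = %g ms)\n",
              x$name, nrow(x$events), heartbeat_cost(x), x$RR))
  for (k in names(counts)) cat(sprintf("  %-10s x %d\n", k, counts[[k]]))
  invisible(x)
}

#' Read or write a protocol as JSON
#'
#' Serializes the event table and timing so a protocol can travel beside a
#' simulated series or be supplied on the command line.
#'
#' @param p A `protocol_spec`.
#' @param path File path to a JSON protocol description.
#' @return `read_protocol()` returns a `protocol_spec`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "protocol_spec"))
  jsonlite::write_json(
    list(name = p$name, RR = p$RR, events = p$events),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(x$events)
  if (is.null(ev$TE_prep)) ev$TE_prep <- NA_real_
  ev$TE_prep <- as.numeric(ev$TE_prep)
  protocol_spec(ev, RR = x$RR, name = x$name)
}

# Effective saturation-to-readout delay per event, ms. Recovery beats before
# saturation are irrelevant (saturation zeroes the magnetization); for
# anchors the recovery beats sit after saturation and extend the delay.
event_delay <- function(events, RR) {
  ifelse(events$kind == "anchor", events$recovery_beats * RR + events$TS, events$TS)
}

# Noise-free mSASHA signal vector for one tissue across a protocol's events.
protocol_signal <- function(p, A, T1, T2 = NA_real_) {
  delay <- event_delay(p$events, p$RR)
  s <- A * (1 - exp(-delay / T1))
  t2p <- p$events$kind == "SR+T2prep"
  if (any(t2p)) {
    if (is.na(T2)) stop("protocol contains T2-prepared events but T2 is missing")
    s[t2p] <- s[t2p] * exp(-p$events$TE_prep[t2p] / T2)
  }
  s
}
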