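#' Per-molecule contact-count trace
#'
#' Heavy-atom contact counts of one amphiphile molecule per trajectory
#' frame (contact convention: heavy atoms within 5 A of the protein, or
#' of a partner amphiphile for bulk pairs).
#'
#' @param q non-negative integer contact counts per frame.
#' @param frame_interval frame spacing (ns), > 0.
#' @param molecule_id integer identifier.
#' @param role `"protein_contact"` (protein-amphiphile) or `"bulk_pair"`
#'   (amphiphile-amphiphile reference).
#' @param part `"whole"`, `"headgroup"` or `"tail"`.
#' @return An object of class `contact_trace`.
#' @export
contact_trace <- function(q, frame_interval, molecule_id = 1L,
                          role = c("protein_contact", "bulk_pair"),
                          part = c("whole", "headgroup", "tail")) {
  role <- match.arg(role); part <- match.arg(part)
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(q = q, frame_interval = frame_interval,
                 molecule_id = as.integer(molecule_id), role = role, part = part),
            class = "contact_trace")
}

#' @export
print.contact_trace <- function(x, ...) {
  cat(sprintf("Contact trace #%d (%s, %s): %d frames x %.3g ns, %d in contact\n",
              x$molecule_id, x$role, x$part, length(x$q), x$frame_interval,
              sum(x$q > 0)))
  invisible(x)
}

#' Detect contact events in a trace
#'
#' A contact event is a maximal run of frames with q > 0, where
#' non-contacting gaps no longer than `gap_threshold` (in ns; the bulk
#' amphiphile relaxation time, by the default convention) are absorbed
#' into the surrounding event. Events are disjoint and ordered. An
#' all-zero trace yields an empty list.
#'
#' @param trace a [contact_trace()].
#' @param gap_threshold maximal non-contacting gap to merge, in ns
#'   (>= 0). Converted to frames by flooring `gap_threshold /
#'   frame_interval`.
#' @return data.frame with `start_frame`, `end_frame` (1-based,
#'   inclusive, both in contact), `merged_gaps`, `molecule_id`.
#' @export
detect_contact_events <- function(trace, gap_threshold = 0) {
  stopifnot(inherits(trace, "contact_trace"))
  if (!is.finite(gap_threshold) || gap_threshold < 0)
    stop("gap_threshold must be >= 0")
  gap_frames <- floor(gap_threshold / trace$frame_interval)
  r <- rle(trace$q > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, contact = r$values,
                     len = r$lengths)
  contact_runs <- runs[runs$contact, , drop = FALSE]
  if (!nrow(contact_runs))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      merged_gaps = integer(0), molecule_id = integer(0)))
  # merge consecutive contact runs separated by a short enough zero gap
  out_start <- contact_runs$start[1]; out_end <- contact_runs$end[1]
  merged <- 0L
  events <- list()
  if (nrow(contact_runs) > 1) {
    for (i in 2:nrow(contact_runs)) {
      gap <- contact_runs$start[i] - out_end - 1L
      if (gap <= gap_frames) {
        out_end <- contact_runs$end[i]
        merged <- merged + 1L
      } else {
        events[[length(events) + 1L]] <- c(out_start, out_end, merged)
        out_start <- contact_runs$start[i]; out_end <- contact_runs$end[i]
        merged <- 0L
      }
    }
  }
  events[[length(events) + 1L]] <- c(out_start, out_end, merged)
  m <- do.call(rbind, events)
  data.frame(start_frame = m[, 1], end_frame = m[, 2], merged_gaps = m[, 3],
             molecule_id = trace$molecule_id)
}

#' Contact autocorrelation over events
#'
#' Event-averaged normalized contact autocorrelation
#' \deqn{c(\tau) = \frac{1}{N_c} \sum_{i=1}^{N_c}
#'   \left\langle \frac{q_i(t)\, q_i(t+\tau)}{q_i^2(t)} \right\rangle_t,}
#' where the sum runs over contact events and the time average over
#' origins t inside event i with q_i(t) > 0 (division guard) and t+tau
#' inside the trace. By default (`beyond_event = "event"`) the count
#' series of event i is taken to vanish outside the event, so c(tau) is
#' the event survival-weighted correlation and decays to zero for
#' transient contacts; `beyond_event = "trace"` reads q(t+tau) from the
#' full trace (rebinding after the event then contributes), provided as
#' a diagnostic. c(0) = 1 by construction.
#'
#' @param traces a list of [contact_trace()]s (a single trace is
#'   accepted).
#' @param max_lag maximal lag (ns); must be below the trace duration.
#' @param gap_threshold event-merging gap threshold (ns), passed to
#'   [detect_contact_events()].
#' @param lag_step lag spacing (ns); defaults to one frame interval.
#' @param beyond_event `"event"` (default) or `"trace"`, see above.
#' @param weighting `"origin"` (default) pools all valid origins across
#'   events, so c(tau) is the residual-lifetime survival correlation
#'   (decaying as exp(-k_off tau) for exponential dwell times, which is
#'   what the 1/e residence time estimates); `"event"` gives each event
#'   equal weight regardless of its length (the literal per-event mean),
#'   which down-weights long events and decays faster.
#' @return An object of class `autocorr_result` with `tau` (ns), `c`,
#'   and `n_events`.
#' @export
contact_autocorr <- function(traces, max_lag, gap_threshold = 0,
                             lag_step = NULL,
                             beyond_event = c("event", "trace"),
                             weighting = c("origin", "event")) {
  beyond_event <- match.arg(beyond_event)
  weighting <- match.arg(weighting)
  if (inherits(traces, "contact_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, all(vapply(traces, inherits, TRUE, "contact_trace")))
  dt <- traces[[1]]$frame_interval
  if (!all(vapply(traces, function(tr) tr$frame_interval, 1) == dt))
    stop("all traces must share one frame_interval")
  dur <- min(vapply(traces, function(tr) length(tr$q), 1L)) * dt
  if (!is.finite(max_lag) || max_lag <= 0 || max_lag >= dur)
    stop("max_lag must be positive and below the trace duration")
  step_frames <- max(1L, round((lag_step %||% dt) / dt))
  lag_frames <- seq(0L, floor(max_lag / dt), by = step_frames)

  num <- numeric(length(lag_frames)); den <- numeric(length(lag_frames))
  n_events <- 0L
  for (tr in traces) {
    ev <- detect_contact_events(tr, gap_threshold)
    if (!nrow(ev)) next
    n_frames <- length(tr$q)
    for (k in seq_len(nrow(ev))) {
      s <- ev$start_frame[k]; e <- ev$end_frame[k]
      qev <- tr$q[s:e]
      origins <- which(qev > 0)            # origins with q_i(t) > 0
      if (!length(origins)) next
      n_events <- n_events + 1L
      # q(t) q(t+tau) / q(t)^2 simplifies to q(t+tau) / q(t) on guarded origins
      qsrc <- if (beyond_event == "event") {
        c(qev, numeric(max(lag_frames)))   # event series vanishes past its end
      } else {
        c(tr$q[s:n_frames], numeric(max(lag_frames)))
      }
      for (j in seq_along(lag_frames)) {
        lf <- lag_frames[j]
        tt <- origins[(s + origins - 1L + lf) <= n_frames]  # t + tau inside trace
        if (!length(tt)) next
        ratios <- qsrc[tt + lf] / qev[tt]
        if (weighting == "origin") {
          num[j] <- num[j] + sum(ratios)
          den[j] <- den[j] + length(ratios)
        } else {
          num[j] <- num[j] + mean(ratios)
          den[j] <- den[j] + 1
        }
      }
    }
  }
  if (n_events == 0L) stop("no contact events found (N_c = 0)")
  cvals <- ifelse(den > 0, num / den, NA_real_)
  structure(list(tau = lag_frames * dt, c = cvals, n_events = n_events),
            class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("Contact autocorrelation: %d events, %d lags up to %.3g ns, c(max) = %.3g\n",
              x$n_events, length(x$tau), max(x$tau), x$c[length(x$c)]))
  invisible(x)
}
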