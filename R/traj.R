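#' Assign binding-site states along a trajectory
#'
#' Frame-wise labeling of the ion coordinate into the binding-site
#' states {deep, allosteric, transient, bulk} by sorted z cutpoints,
#' followed by debouncing: excursions shorter than `min_dwell` frames
#' are merged into the surrounding state, suppressing barrier-top
#' recrossings. The default cutpoints place the deep site below
#' -1 A, the allosteric site around the crystallographic z = 0, the
#' transient (orthosteric-pocket) site between 3 and 12.5 A, and bulk
#' beyond.
#'
#' @param traj a [trajectory1d] (or numeric z vector).
#' @param boundaries sorted z cutpoints separating the states.
#' @param labels state names, length = length(boundaries) + 1.
#' @param min_dwell minimum dwell (frames) for a state visit to count.
#' @return object of class `state_sequence`: list(states (factor),
#'   boundaries, labels, min_dwell, dt).
#' @export
assign_states <- function(traj,
                          boundaries = c(-1.0, 3.0, 12.5),
                          labels = c("deep", "allosteric", "transient", "bulk"),
                          min_dwell = 100) {
  z <- if (inherits(traj, "trajectory1d")) traj$z else as.numeric(traj)
  dt <- if (inherits(traj, "trajectory1d")) traj$dt else NA_real_
  if (!length(boundaries)) stop("empty boundaries")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be sorted")
  if (length(labels) != length(boundaries) + 1)
    stop("need one more label than boundaries")
  idx <- findInterval(z, boundaries) + 1L
  idx <- .debounce(idx, min_dwell)
  structure(list(states = factor(labels[idx], levels = labels),
                 boundaries = boundaries, labels = labels,
                 min_dwell = min_dwell, dt = dt),
            class = "state_sequence")
}

# merge runs shorter than min_dwell into the preceding surviving state
# (the leading run always survives); iterate until fixed point
.debounce <- function(idx, min_dwell) {
  if (min_dwell <= 1) return(idx)
  repeat {
    r <- rle(idx)
    short <- which(r$lengths < min_dwell)
    short <- setdiff(short, 1L)
    if (!length(short)) return(inverse.rle(r))
    r$values[short[1]] <- r$values[short[1] - 1L]
    idx <- inverse.rle(r)
  }
}

#' @export
print.state_sequence <- function(x, ...) {
  tb <- table(x$states)
  cat(sprintf("<state_sequence> %d frames (min_dwell %d): %s\n",
              length(x$states), x$min_dwell,
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Detect state transitions and annotate them with V_m
#'
#' One event per debounced label change. When a voltage series is
#' supplied it is smoothed with [windowed_average] first and the event
#' is annotated with the smoothed voltage at the event time (the
#' approximate V_m at the transition, not the instantaneous value).
#'
#' @param states a `state_sequence` from [assign_states].
#' @param vm_series optional numeric voltage series (mV) aligned
#'   frame-by-frame with the trajectory the states came from.
#' @param vm_window smoothing window for the voltage annotation, in
#'   frames (default 200).
#' @return data.frame(time_frame, time, from_state, to_state, vm_mV);
#'   zero rows when no transitions occur.
#' @export
detect_transitions <- function(states, vm_series = NULL, vm_window = 200) {
  stopifnot(inherits(states, "state_sequence"))
  s <- as.integer(states$states)
  n <- length(s)
  if (!is.null(vm_series) && length(vm_series) != n)
    stop("length mismatch between states and vm_series")
  chg <- which(diff(s) != 0) + 1L
  vm_at <- rep(NA_real_, length(chg))
  if (!is.null(vm_series) && length(chg)) {
    w <- min(vm_window, n)
    sm <- windowed_average(vm_series, dt = 1, window = w,
                           running_mean = w / 2)
    vm_at <- stats::approx(sm$time, sm$value, xout = chg - 1,
                           rule = 2)$y
  }
  dt <- if (is.na(states$dt)) 1 else states$dt
  data.frame(
    time_frame = chg,
    time = (chg - 1) * dt,
    from_state = states$labels[s[pmax(chg - 1L, 1L)]],
    to_state = states$labels[s[chg]],
    vm_mV = vm_at,
    stringsAsFactors = FALSE)
}

#' First-passage statistics over replicate transition sets
#'
#' Aggregates replicate trajectories at one condition: the time of
#' each replicate's first transition into `target` (NA if it never
#' arrives) summarized as median, IQR and the fraction of replicates
#' that transitioned within the horizon.
#'
#' @param events_list list of transition data.frames (one per
#'   replicate) as returned by [detect_transitions].
#' @param target destination state of interest (default "transient").
#' @param horizon time horizon; defaults to Inf (any recorded event
#'   counts).
#' @return list(n, fraction_transitioned, median_time, iqr_time,
#'   times).
#' @export
transition_statistics <- function(events_list, target = "transient",
                                  horizon = Inf) {
  stopifnot(length(events_list) >= 1)
  times <- vapply(events_list, function(ev) {
    hit <- ev$time[ev$to_state == target & ev$time <= horizon]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  ok <- !is.na(times)
  list(n = length(times),
       fraction_transitioned = mean(ok),
       median_time = if (any(ok)) stats::median(times[ok]) else NA_real_,
       iqr_time = if (any(ok)) stats::IQR(times[ok]) else NA_real_,
       times = times)
}
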