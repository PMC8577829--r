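# Closed-form mathematics of RITE tag dilution.
#
# After recombination the old tag (red) is no longer synthesised; every round
# of replication-coupled synthesis deposits the new tag (green, or blue after
# a second Flp switch) and mitosis splits the pool symmetrically, so the old
# tag halves per completed division.

.div_class_labels <- c("0-1", "1-2", "2-3", "3-4", "4+")
.div_class_breaks <- c(0, 0.5, 0.75, 0.875, 0.9375, 1)

#' Division class labels and green-fraction boundaries
#'
#' The five division classes used throughout the package and the
#' green-fraction (R) boundaries separating them: 0-50% (0-1 division),
#' 50-75% (1-2), 75-87.5% (2-3), 87.5-93.75% (3-4), >93.75% (4+).  Intervals
#' are half-open `[lower, upper)`; the top class is closed at 1.
#'
#' @return `division_class_labels()` returns a character vector of length 5;
#'   `division_class_breaks()` returns the numeric boundaries (length 6, on
#'   the fraction scale in `[0, 1]`).
#' @export
division_class_labels <- function() .div_class_labels

#' @rdname division_class_labels
#' @export
division_class_breaks <- function() .div_class_breaks

#' Green-to-total fluorescence fraction after a number of divisions
#'
#' Forward dilution model.  With the old-tag intensity halving per division
#' and the new tag refilling the pool, the green-to-total fraction after `n`
#' completed post-recombination divisions is
#' \deqn{R(n) = \frac{2^n - 1}{C + 2^n - 1},}
#' where `C` is the baseline old-to-new tag intensity ratio (`C = 1` for
#' equally bright reporters).  `R(0) = 0`, `R` is strictly increasing in `n`,
#' and `R -> 1` as `n -> Inf`.
#'
#' @param n non-negative integer vector of completed divisions.
#' @param C positive scalar baseline intensity ratio (old tag / new tag).
#' @return numeric vector of green fractions in `[0, 1)`.
#' @seealso [estimate_divisions()] for the exact inverse,
#'   [classify_division_number()] for class binning.
#' @examples
#' green_fraction_after_divisions(0:4)        # 0, 0.5, 0.75, 0.875, 0.9375
#' green_fraction_after_divisions(2, C = 2)   # 0.6
#' @export
green_fraction_after_divisions <- function(n, C = 1) {
  .check_C(C)
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8)) {
    stop("`n` must be a vector of non-negative integers", call. = FALSE)
  }
  n <- round(n)
  # R = a / (C + a) with a = 2^n - 1, written to stay finite for large n
  a <- expm1(n * log(2))
  ifelse(is.infinite(a), 1, a / (C + a))
}

#' Estimate the division number from a green fraction
#'
#' Exact inverse of [green_fraction_after_divisions()]:
#' \deqn{\hat n = \log_2\!\left(1 + C\,\frac{R}{1-R}\right),}
#' which reduces to \eqn{-\ln(1-R)/\ln 2} when `C = 1`.
#'
#' @param R numeric vector of green fractions in `[0, 1)`.  `R = 1` is
#'   rejected: the estimate is unbounded there (any sufficiently large
#'   division number is indistinguishable).
#' @inheritParams green_fraction_after_divisions
#' @return numeric vector of continuous division estimates (>= 0).
#' @examples
#' estimate_divisions(c(0.5, 0.75, 0.9375))  # 1, 2, 4
#' @export
estimate_divisions <- function(R, C = 1) {
  .check_C(C)
  .check_R(R)
  if (any(R == 1)) {
    stop("R = 1 is unbounded: the division estimate diverges", call. = FALSE)
  }
  log1p(C * R / (1 - R)) / log(2)
}

#' Assign a division class from a green fraction
#'
#' Bins the green fraction `R` into the five division classes using the
#' boundaries 50%, 75%, 87.5% and 93.75% (see [division_class_labels()]).
#' Classes are half-open `[lower, upper)`, so `R = 0.75` falls in "2-3"; the
#' top class "4+" covers `[0.9375, 1]`.  Equivalent to
#' `min(floor(estimate_divisions(R, 1)), 4)` mapped to its label.
#'
#' @param R numeric vector of green fractions in `[0, 1]`.
#' @return factor with levels `division_class_labels()`.
#' @export
classify_division_number <- function(R) {
  .check_R(R, allow_one = TRUE)
  idx <- findInterval(R, .div_class_breaks, rightmost.closed = TRUE)
  factor(.div_class_labels[idx], levels = .div_class_labels)
}

.check_C <- function(C) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("`C` must be a single positive number", call. = FALSE)
  }
}

.check_R <- function(R, allow_one = TRUE) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R < 0) || any(R > 1)) {
    stop("`R` must lie in [0, 1]", call. = FALSE)
  }
}

#' Deterministic theoretical reporter trajectory
#'
#' Constructs the idealised per-cell fluorescence time course used as the
#' reference for live-imaging data.  The old tag (red) starts at `pool`
#' (= 100 by default) and halves instantaneously at every division; during
#' each inter-division cycle the currently synthesised tag rises linearly
#' from its post-division value so that the channel sum is restored to
#' `pool` by the next division instant.  With equal cycle lengths this gives
#' the classic series red 100, 50, 25, ... and green 0 -> 50, drop to 25,
#' rise to 75, drop to 37.5, rise to 87.5, ...
#'
#' If `flp_time` is given, synthesis switches from green to blue at that
#' instant (a second recombination): green stops refilling and thereafter
#' halves per division like red, while blue completes the pool.
#'
#' @param division_times strictly increasing numeric vector of division
#'   instants (hours); all must be at or after `recombination_time`.
#' @param recombination_time hour of the red-to-green switch; must not exceed
#'   the first division time.
#' @param flp_time optional hour of the green-to-blue switch (`NULL` for the
#'   two-colour reporter; must be greater than `recombination_time`).
#' @param sample_step sampling interval of the returned time grid (hours).
#' @param detection_delay hours between synthesis onset and detectable new
#'   tag; shifts the start of the first green ramp (default 0, i.e. none).
#' @param horizon end of the trajectory; defaults to one mean cycle length
#'   after the last division so the final refill is visible.
#' @param pool full histone-pool level in normalized units (default 100).
#' @return an object of class `icount_trajectory`: a list with `samples`
#'   (data frame of `time`, `red`, `green`, and `blue` when `flp_time` is
#'   given; values at division instants are the post-division values),
#'   `division_times`, `segments` (exact piecewise-linear description), and
#'   the model parameters.
#' @seealso [trajectory_value()] for exact left/right limits,
#'   [interval_mean_trajectory()] for per-cycle channel means.
#' @examples
#' traj <- theoretical_trajectory(c(16, 32, 48, 64))
#' trajectory_value(traj, 48, "right")["green"]  # 37.5
#' trajectory_value(traj, 64, "left")["green"]   # 87.5
#' @export
theoretical_trajectory <- function(division_times, recombination_time = 0,
                                   flp_time = NULL, sample_step = 0.5,
                                   detection_delay = 0, horizon = NULL,
                                   pool = 100) {
  if (!is.numeric(division_times) || length(division_times) < 1L ||
      any(!is.finite(division_times))) {
    stop("`division_times` must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  if (is.unsorted(division_times, strictly = TRUE)) {
    stop("`division_times` must be strictly increasing", call. = FALSE)
  }
  if (recombination_time > division_times[1L]) {
    stop("`recombination_time` must not exceed the first division time",
         call. = FALSE)
  }
  if (sample_step <= 0) stop("`sample_step` must be positive", call. = FALSE)
  if (detection_delay < 0) {
    stop("`detection_delay` must be non-negative", call. = FALSE)
  }
  if (!is.null(flp_time) && flp_time <= recombination_time) {
    stop("`flp_time` must be after `recombination_time`", call. = FALSE)
  }
  K <- length(division_times)
  mean_cycle <- mean(diff(c(recombination_time, division_times)))
  if (is.null(horizon)) horizon <- division_times[K] + mean_cycle
  if (horizon <= division_times[K]) {
    stop("`horizon` must be after the last division", call. = FALSE)
  }

  three_col <- !is.null(flp_time)
  bounds <- c(recombination_time, division_times, horizon)
  state <- c(red = pool, green = 0, blue = 0)
  rows <- vector("list", 4L * (K + 1L))
  nrow_ <- 0L
  add_row <- function(k, a, b, s0, s1) {
    nrow_ <<- nrow_ + 1L
    rows[[nrow_]] <<- data.frame(
      interval = k, t_start = a, t_end = b,
      red_start = s0[["red"]], red_end = s1[["red"]],
      green_start = s0[["green"]], green_end = s1[["green"]],
      blue_start = s0[["blue"]], blue_end = s1[["blue"]])
  }
  green_onset_pending <- detection_delay > 0

  for (k in 0:K) {
    t0 <- bounds[k + 1L]
    t1 <- bounds[k + 2L]
    deficit <- pool - sum(state)
    ramp_start <- t0
    if (deficit > 1e-12 && green_onset_pending &&
        (is.null(flp_time) || t0 < flp_time)) {
      # delayed first appearance of the new green tag
      ramp_start <- min(t0 + detection_delay, t1)
      if (ramp_start > t0) add_row(k, t0, ramp_start, state, state)
      green_onset_pending <- FALSE
    }
    refill <- if (t1 > ramp_start) deficit else 0
    rate <- if (t1 > ramp_start) refill / (t1 - ramp_start) else 0
    cut <- if (three_col && flp_time > ramp_start && flp_time < t1) {
      flp_time
    } else {
      NULL
    }
    synth1 <- if (three_col && ramp_start >= flp_time) "blue" else "green"
    if (is.null(cut)) {
      if (t1 > ramp_start) {
        s1 <- state
        s1[[synth1]] <- s1[[synth1]] + refill
        add_row(k, ramp_start, t1, state, s1)
        state <- s1
      }
    } else {
      s_mid <- state
      s_mid[["green"]] <- s_mid[["green"]] + rate * (cut - ramp_start)
      add_row(k, ramp_start, cut, state, s_mid)
      s_end <- s_mid
      s_end[["blue"]] <- s_end[["blue"]] + rate * (t1 - cut)
      add_row(k, cut, t1, s_mid, s_end)
      state <- s_end
    }
    if (k < K) state <- state / 2  # instantaneous symmetric division
  }
  segments <- do.call(rbind, rows[seq_len(nrow_)])

  out <- structure(
    list(segments = segments, division_times = division_times,
         recombination_time = recombination_time, flp_time = flp_time,
         horizon = horizon, pool = pool, detection_delay = detection_delay),
    class = "icount_trajectory")
  times <- sort(unique(c(seq(recombination_time, horizon, by = sample_step),
                         division_times, horizon)))
  vals <- vapply(times, function(t) trajectory_value(out, t, "right"),
                 numeric(3L))
  samples <- data.frame(time = times, red = vals["red", ],
                        green = vals["green", ])
  if (three_col) samples$blue <- vals["blue", ]
  out$samples <- samples
  out
}

#' Evaluate a theoretical trajectory at a time point
#'
#' Divisions are instantaneous, so channel values are discontinuous at
#' division instants; `side` selects the pre-division ("left") or
#' post-division ("right", the default) value.
#'
#' @param traj an `icount_trajectory`.
#' @param time a single time in hours within the trajectory's range.
#' @param side `"right"` (value just after `time`) or `"left"` (just before).
#' @return named numeric vector with elements `red`, `green`, `blue`.
#' @export
trajectory_value <- function(traj, time, side = c("right", "left")) {
  stopifnot(inherits(traj, "icount_trajectory"), length(time) == 1L)
  side <- match.arg(side)
  seg <- traj$segments
  i <- if (side == "right") {
    which(seg$t_start <= time & time < seg$t_end)
  } else {
    which(seg$t_start < time & time <= seg$t_end)
  }
  if (length(i) == 0L) {
    # the horizon itself (right side) or the origin (left side)
    i <- if (side == "right") nrow(seg) else 1L
    if (time < seg$t_start[1L] || time > seg$t_end[nrow(seg)]) {
      stop("`time` outside the trajectory range", call. = FALSE)
    }
  }
  i <- i[1L]
  span <- seg$t_end[i] - seg$t_start[i]
  w <- if (span > 0) (time - seg$t_start[i]) / span else 0
  c(red = seg$red_start[i] + w * (seg$red_end[i] - seg$red_start[i]),
    green = seg$green_start[i] + w * (seg$green_end[i] - seg$green_start[i]),
    blue = seg$blue_start[i] + w * (seg$blue_end[i] - seg$blue_start[i]))
}

#' Per-interval channel means of a theoretical trajectory
#'
#' Arithmetic time-average of each channel over the `k`-th inter-division
#' interval, computed exactly from the piecewise-linear segments (the mean of
#' a linear ramp is its midpoint).  Interval `k = 0` spans recombination to
#' the first division (red constant at the full pool, green 0); interval
#' `k = 1` is the first green ramp 0 -> 50 with mean 25; interval `k = 2`
#' ramps 25 -> 75 with mean 50.
#'
#' @param traj an `icount_trajectory`.
#' @param k interval index: number of completed divisions during the
#'   interval, from 0 to `length(division_times)`.
#' @return named numeric vector of per-channel means (`red`, `green`, and
#'   `blue` for three-colour trajectories).
#' @export
interval_mean_trajectory <- function(traj, k) {
  stopifnot(inherits(traj, "icount_trajectory"))
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0 ||
      k > length(traj$division_times)) {
    stop("`k` must index an inter-division interval present in the trajectory",
         call. = FALSE)
  }
  seg <- traj$segments[traj$segments$interval == k, , drop = FALSE]
  dur <- seg$t_end - seg$t_start
  avg <- function(a, b) sum(dur * (a + b) / 2) / sum(dur)
  out <- c(red = avg(seg$red_start, seg$red_end),
           green = avg(seg$green_start, seg$green_end))
  if (!is.null(traj$flp_time)) {
    out <- c(out, blue = avg(seg$blue_start, seg$blue_end))
  }
  out
}

#' @export
print.icount_trajectory <- function(x, ...) {
  cat("Theoretical reporter trajectory\n")
  cat(sprintf("  %d divisions, recombination at %g h%s, pool %g\n",
              length(x$division_times), x$recombination_time,
              if (!is.null(x$flp_time)) {
                sprintf(", Flp switch at %g h", x$flp_time)
              } else "",
              x$pool))
  cat(sprintf("  sampled %d time points over [%g, %g] h\n",
              nrow(x$samples), x$recombination_time, x$horizon))
  invisible(x)
}

#' @export
as.data.frame.icount_trajectory <- function(x, ...) x$samples

#' Write a theoretical trajectory as delimited text
#'
#' @param traj an `icount_trajectory`.
#' @param path output file path (CSV with columns `time`, `red`, `green`, and
#'   `blue` for three-colour trajectories).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "icount_trajectory"))
  write.csv(traj$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state three-colour fractions of the two-switch reporter
#'
#' Closed-form pool fractions of a miCOUNT-type reporter measured at cycle
#' completion after `n_pre` divisions between the Cre (red -> green) and Flp
#' (green -> blue) switches and `n_post` divisions after Flp, assuming equal
#' baseline intensities:
#' \deqn{red = 2^{-(n_{pre}+n_{post})},\quad
#'       green = (1 - 2^{-n_{pre}})\,2^{-n_{post}},\quad
#'       blue = 1 - 2^{-n_{post}}.}
#' The three fractions sum to one.
#'
#' @param n_pre,n_post non-negative integers.
#' @return named numeric vector `c(red, green, blue)`.
#' @examples
#' micount_fractions(1, 1)  # 0.25 0.25 0.50
#' @export
micount_fractions <- function(n_pre, n_post) {
  for (v in list(n_pre, n_post)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v)) {
      stop("division counts must be single non-negative integers",
           call. = FALSE)
    }
  }
  red <- 2^-(n_pre + n_post)
  green <- (1 - 2^-n_pre) * 2^-n_post
  blue <- 1 - 2^-n_post
  c(red = red, green = green, blue = blue)
}
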