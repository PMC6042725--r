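# Kinematic preprocessing: tag frame -> whale frame, low/high frequency
# separation, pitch/roll, dive and phase segmentation, stroke/glide/lunge
# detection and speed determination.

#' Rotation matrix from roll / pitch / yaw angles
#'
#' Intrinsic z-y-x (yaw, pitch, roll) rotation; used to describe tag mounting
#' orientations. All angles in radians.
#'
#' @param roll,pitch,yaw Rotation angles about the surge, sway and heave axes.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(roll = 0, pitch = 0, yaw = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(roll), -sin(roll)), c(0, sin(roll), cos(roll)))
  Ry <- rbind(c(cos(pitch), 0, sin(pitch)), c(0, 1, 0), c(-sin(pitch), 0, cos(pitch)))
  Rz <- rbind(c(cos(yaw), -sin(yaw), 0), c(sin(yaw), cos(yaw), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotate tag-frame acceleration into the whale frame
#'
#' Tags attach at arbitrary orientations, so recorded acceleration must be
#' rotated into a whale-centred frame: surge along the body long axis,
#' positive forward; heave dorso-ventral, positive up at rest. With
#' `orientation = "auto"` the gravity direction is estimated as the median
#' unit acceleration over near-surface, low-activity samples and rotated onto
#' the heave axis (the yaw about gravity is unobservable from acceleration
#' alone and is left at zero). A user-supplied rotation matrix always takes
#' precedence.
#'
#' @param record A [tag_record()] with a calibrated depth channel (required
#'   for `"auto"`).
#' @param orientation A 3x3 rotation matrix applied as
#'   `a_whale = R %*% a_tag`, or `"auto"`.
#' @param surface_max_depth Depth below which samples count as surface, m.
#' @param quiet_quantile Quantile of high-frequency energy below which surface
#'   samples count as low-activity.
#' @return The record with `accel` rotated; the rotation used is stored in
#'   `record$orientation`.
#' @export
rotate_to_whale_frame <- function(record, orientation = "auto",
                                  surface_max_depth = 1,
                                  quiet_quantile = 0.5) {
  if (is.character(orientation) && identical(orientation, "auto")) {
    R <- estimate_tag_orientation(record, surface_max_depth, quiet_quantile)
  } else {
    R <- as.matrix(orientation)
    if (!all(dim(R) == c(3, 3)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("orientation must be a 3x3 orthonormal rotation matrix")
  }
  record$accel <- record$accel %*% t(R)
  record$orientation <- R
  record
}

#' Estimate tag mounting orientation from surface intervals
#'
#' @inheritParams rotate_to_whale_frame
#' @return A 3x3 rotation matrix mapping tag-frame to whale-frame
#'   acceleration.
#' @export
estimate_tag_orientation <- function(record, surface_max_depth = 1,
                                     quiet_quantile = 0.5) {
  if (is.null(record$depth))
    stop("auto orientation needs a calibrated depth channel")
  d_at_accel <- stats::approx(record$time, record$depth, record$accel_time,
                              rule = 2)$y
  surf <- d_at_accel < surface_max_depth
  if (!any(surf))
    stop("auto orientation: no surface (depth < ", surface_max_depth,
         " m) samples found to estimate the gravity direction")
  # low-activity = smallest deviation of |a| from g among surface samples
  nrm <- sqrt(rowSums(record$accel^2))
  dev <- abs(nrm - 9.8)
  keep <- surf & dev <= stats::quantile(dev[surf], quiet_quantile)
  if (!any(keep))
    stop("auto orientation: no low-activity surface segment found")
  gdir <- apply(record$accel[keep, , drop = FALSE] / nrm[keep], 2,
                stats::median)
  gdir <- gdir / sqrt(sum(gdir^2))
  rotation_aligning(gdir, c(0, 0, 1))
}

# minimal rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_aligning <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2)); c_ <- sum(u * v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u; w <- w / sqrt(sum(w^2))
    K <- skew(w)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew(w / s)
  diag(3) + s * K + (1 - c_) * K %*% K
}

skew <- function(w) rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))

#' Separate gravitational and specific acceleration
#'
#' Posture changes are slow relative to propulsive movements, so a zero-phase
#' (forward-backward) low-pass FIR filter splits each acceleration axis into a
#' low-frequency (gravitational / postural) and a high-frequency (specific,
#' e.g. stroking) component. The two components sum exactly to the input.
#'
#' @param accel Numeric matrix, 3 columns, m s^-2.
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Low-pass cutoff, Hz; default 0.135 (midpoint of the
#'   0.12-0.15 Hz range used across deployments). Must be below Nyquist.
#' @param transition_hz Target transition-band width used to choose the filter
#'   order, Hz.
#' @param order Optional explicit FIR order (overrides `transition_hz`); it is
#'   reduced automatically if the record is too short for forward-backward
#'   filtering at the requested order.
#' @return A list with matrices `low` and `high` (`low + high` equals the
#'   input) and the `order` used.
#' @export
separate_acceleration <- function(accel, rate, cutoff_hz = 0.135,
                                  transition_hz = 0.05, order = NULL) {
  accel <- as.matrix(accel)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff_hz must lie strictly between 0 and Nyquist (", rate / 2, " Hz)")
  n <- nrow(accel)
  if (is.null(order)) order <- ceiling(3.3 * rate / transition_hz)
  order <- min(order, max(2, floor((n - 1) / 3)))
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, cutoff_hz / (rate / 2), type = "low")
  h <- h / sum(h)   # unit DC gain: a constant input passes unchanged
  low <- apply(accel, 2, function(x) zero_phase_filter(x, h))
  low <- matrix(low, ncol = ncol(accel))
  list(low = low, high = accel - low, order = order)
}

# forward-backward filtering with odd-reflection end padding, so that edge
# transients fall in the padding, not the data
zero_phase_filter <- function(x, h) {
  n <- length(x)
  np <- min(length(h), n - 1)
  xe <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filtfilt(h, xe)
  y[(np + 1):(np + n)]
}

#' Pitch and roll from the gravitational acceleration component
#'
#' With the low-frequency component approximating the gravity reaction in the
#' whale frame (surge, sway, heave), pitch is the angle of the surge axis
#' above horizontal, positive nose-up, and roll is the rotation about the
#' surge axis. Samples whose acceleration norm is outside `norm_range` times
#' standard gravity are returned as `NA` rather than fabricating angles.
#'
#' @param low_accel Low-frequency acceleration matrix (surge, sway, heave),
#'   m s^-2.
#' @param norm_range Acceptable |a|/g range; default `c(0.5, 1.5)`.
#' @param g Standard gravity, m s^-2.
#' @return A list with numeric vectors `pitch` and `roll`, radians;
#'   `|pitch| <= pi/2`.
#' @examples
#' compute_pitch_roll(matrix(c(9.8 * sin(pi / 6), 0, 9.8 * cos(pi / 6)), 1))
#' @export
compute_pitch_roll <- function(low_accel, norm_range = c(0.5, 1.5), g = 9.8) {
  low_accel <- as.matrix(low_accel)
  nrm <- sqrt(rowSums(low_accel^2))
  ok <- nrm > norm_range[1] * g & nrm < norm_range[2] * g
  pitch <- ifelse(ok, atan2(low_accel[, 1],
                            sqrt(low_accel[, 2]^2 + low_accel[, 3]^2)), NA_real_)
  roll <- ifelse(ok, atan2(low_accel[, 2], low_accel[, 3]), NA_real_)
  list(pitch = pitch, roll = roll)
}

#' Detect dives in a depth series
#'
#' A dive is any submergence to a depth greater than `threshold_m` (10 m by
#' default); its extent is the maximal interval between surface crossings
#' containing that submergence.
#'
#' @param time Time, s.
#' @param depth Depth, m, positive down.
#' @param threshold_m Minimum maximum-depth for an excursion to count as a
#'   dive, m.
#' @param surface_m Depth below which the animal is considered at the
#'   surface, m.
#' @return A data frame with columns `dive_id`, `start_time`, `end_time`,
#'   `max_depth` (zero rows if there are no dives).
#' @export
detect_dives <- function(time, depth, threshold_m = 10, surface_m = 1) {
  stopifnot(length(time) == length(depth), all(is.finite(depth)))
  sub <- depth > surface_m
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  id <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts[k]:ends[k]
    if (max(depth[i]) > threshold_m) {
      id <- id + 1L
      out[[id]] <- data.frame(dive_id = id,
                              start_time = time[i[1]],
                              end_time = time[i[length(i)]],
                              max_depth = max(depth[i]))
    }
  }
  if (id == 0L)
    return(data.frame(dive_id = integer(), start_time = numeric(),
                      end_time = numeric(), max_depth = numeric()))
  do.call(rbind, out)
}

#' Segment a dive into descent, bottom and ascent phases
#'
#' Phases are delimited by smoothed-pitch threshold crossings: descent runs
#' from the start of the dive until smoothed pitch first rises above
#' `descent_exit_deg`; ascent runs from the last time smoothed pitch was below
#' `ascent_entry_deg` to the end of the dive; bottom is the remainder. If the
#' pitch never crosses the thresholds the dive is split at its depth maximum
#' with an empty bottom phase and `flagged = TRUE`.
#'
#' @param time,depth,pitch Series restricted to one dive (s, m, radians).
#' @param descent_exit_deg Smoothed-pitch threshold ending the descent,
#'   degrees.
#' @param ascent_entry_deg Smoothed-pitch threshold starting the ascent,
#'   degrees.
#' @param smooth_s Width of the moving-average pitch smoother, s.
#' @return A data frame with one row per phase (`phase`, `start_time`,
#'   `end_time`, `flagged`); the bottom row is absent when the bottom phase is
#'   empty.
#' @export
segment_dive_phases <- function(time, depth, pitch,
                                descent_exit_deg = -10,
                                ascent_entry_deg = 10,
                                smooth_s = 5) {
  n <- length(time)
  stopifnot(length(depth) == n, length(pitch) == n, n >= 2)
  dt <- stats::median(diff(time))
  w <- max(1L, round(smooth_s / dt))
  sp <- running_mean(ifelse(is.na(pitch), 0, pitch), w) * 180 / pi
  above <- which(sp > descent_exit_deg)
  below <- which(sp < ascent_entry_deg)
  flagged <- FALSE
  if (length(above) == 0 || length(below) == 0) {
    imax <- which.max(depth)
    i_desc_end <- imax; i_asc_start <- imax
    flagged <- TRUE
  } else {
    i_desc_end <- above[1]
    i_asc_start <- below[length(below)]
    if (i_asc_start < i_desc_end) {   # crossings out of order: degenerate
      imax <- which.max(depth)
      i_desc_end <- imax; i_asc_start <- imax
      flagged <- TRUE
    }
  }
  phases <- data.frame(
    phase = c("descent", "bottom", "ascent"),
    start_time = c(time[1], time[i_desc_end], time[i_asc_start]),
    end_time = c(time[i_desc_end], time[i_asc_start], time[n]),
    flagged = flagged)
  # a bottom shorter than the pitch smoother's resolution is an artefact of
  # the threshold crossings, not a real bottom phase
  keep_bottom <- phases$end_time[2] - phases$start_time[2] > smooth_s
  phases[keep_bottom | phases$phase != "bottom", ]
}

# centred running mean, window w samples
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

# centred running max, window w samples; O(n) block prefix/suffix maxima
running_max <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  half <- w %/% 2
  width <- 2L * half + 1L
  nb <- ceiling(n / width)
  pad <- nb * width - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = width)
  pre <- apply(m, 2, cummax)
  suf <- apply(m[width:1, , drop = FALSE], 2, cummax)[width:1, , drop = FALSE]
  pre <- as.vector(pre); suf <- as.vector(suf)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  pmax(suf[lo], pre[hi])
}

#' Detect stroking and gliding from high-frequency acceleration
#'
#' A sample is stroking when the envelope (centred running maximum of the
#' rectified signal over `window_s` seconds) of any configured axis exceeds
#' `threshold`; gliding periods are the maximal non-stroking runs.
#' Impeller-speed tags use the surge axis only; depth-rate-speed tags use
#' surge and the dorso-ventral (heave) axis.
#'
#' @param high_accel High-frequency acceleration matrix (surge, sway, heave),
#'   m s^-2.
#' @param time Time stamps of the rows, s.
#' @param threshold Stroke-detection threshold, m s^-2 (set per deployment,
#'   typically 0.1-0.2).
#' @param axes Columns to inspect; default `c(1, 3)` (surge + heave).
#' @param window_s Envelope window, s.
#' @return A list with logical vector `stroking` and data frame `glides`
#'   (`start_time`, `end_time`, `duration`).
#' @export
detect_strokes <- function(high_accel, time, threshold = 0.15,
                           axes = c(1, 3), window_s = 2) {
  stopifnot(threshold > 0)
  high_accel <- as.matrix(high_accel)
  dt <- stats::median(diff(time))
  w <- max(1L, round(window_s / dt))
  stroking <- rep(FALSE, nrow(high_accel))
  for (j in axes)
    stroking <- stroking | running_max(abs(high_accel[, j]), w) > threshold
  r <- rle(!stroking)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  gl <- data.frame(start_time = time[starts[r$values]],
                   end_time = time[ends[r$values]])
  gl$duration <- gl$end_time - gl$start_time
  list(stroking = stroking, glides = gl)
}

#' Calibrate impeller rotation rate against depth-derived speed
#'
#' Impeller rotation correlates linearly with flow speed. The calibration
#' regresses speed computed as |vertical depth change| / |sin(pitch)| over
#' consecutive `interval_s`-second intervals whose mean |sin(pitch)| exceeds
#' `sin_pitch_min`, against the mean rotation rate in the same intervals
#' (ordinary least squares with intercept).
#'
#' @param time,depth,pitch,impeller Series on the depth-rate grid (s, m,
#'   radians, rotations s^-1).
#' @param sin_pitch_min Steepness criterion for calibration intervals
#'   (0.7-0.9 across deployments; default 0.8).
#' @param interval_s Calibration interval length, s.
#' @param min_intervals Minimum number of qualifying intervals.
#' @param min_depth_m Intervals touching shallower depths are excluded:
#'   near the surface the vertical-speed reference breaks down (and
#'   impellers aerate), so calibration uses submerged steep travel only.
#' @return A list with `slope`, `intercept`, `n_intervals`, and `speed` (the
#'   calibrated speed series, floored at zero).
#' @export
calibrate_impeller_speed <- function(time, depth, pitch, impeller,
                                     sin_pitch_min = 0.8, interval_s = 5,
                                     min_intervals = 10, min_depth_m = 5) {
  stopifnot(!is.null(impeller))
  bins <- floor((time - time[1]) / interval_s)
  sp <- sin(pitch)
  agg <- function(x) tapply(x, bins, mean, na.rm = TRUE)
  msin <- agg(sp)
  rot <- agg(impeller)
  ddep <- tapply(depth, bins, function(z) z[length(z)] - z[1])
  dtim <- tapply(time, bins, function(z) z[length(z)] - z[1])
  dmin <- tapply(depth, bins, min)
  ok <- is.finite(msin) & abs(msin) > sin_pitch_min & is.finite(rot) &
    is.finite(ddep) & dtim > 0 & dmin > min_depth_m
  vtrue <- abs(ddep / dtim) / abs(msin)
  n_ok <- sum(ok)
  if (n_ok < min_intervals)
    stop("impeller calibration not applicable: only ", n_ok,
         " qualifying 5-s intervals (need >= ", min_intervals, ")")
  if (stats::sd(rot[ok]) < 1e-9)
    stop("impeller calibration not applicable: no spread in rotation rate ",
         "across the ", n_ok, " qualifying intervals")
  fit <- stats::lm(vtrue[ok] ~ rot[ok])
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  list(slope = slope, intercept = intercept, n_intervals = n_ok,
       speed = pmax(0, slope * impeller + intercept))
}

#' Glide speed from depth rate and pitch
#'
#' For tags without a speed sensor, speed during steep glides is the rate of
#' change of depth divided by |sin(pitch)|. Samples with |pitch| at or below
#' `min_pitch_deg` are returned as `NA` (the same steepness floor as the
#' sub-glide pitch filter).
#'
#' @param time,depth,pitch Series on the depth-rate grid.
#' @param min_pitch_deg Minimum |pitch| for a defined speed, degrees.
#' @return Speed series, m s^-1, `NA` where undefined.
#' @export
speed_from_depth_rate <- function(time, depth, pitch, min_pitch_deg = 30) {
  n <- length(depth)
  stopifnot(length(time) == n, length(pitch) == n)
  dz <- rep(NA_real_, n)
  if (n >= 2) {
    dz[2:(n - 1)] <- (depth[3:n] - depth[1:(n - 2)]) /
      (time[3:n] - time[1:(n - 2)])
    dz[1] <- (depth[2] - depth[1]) / (time[2] - time[1])
    dz[n] <- (depth[n] - depth[n - 1]) / (time[n] - time[n - 1])
  }
  ok <- !is.na(pitch) & abs(pitch) > min_pitch_deg * pi / 180
  ifelse(ok, abs(dz) / abs(sin(pitch)), NA_real_)
}

#' Detect lunge-feeding events
#'
#' Two detectors are provided. `"speed-peak"`: local speed maxima exceeding
#' the deployment mean plus two standard deviations, followed within
#' `window_s` seconds by a deceleration of at least `decel_frac` of the peak
#' speed. `"jerk-peak"`: local maxima of the jerk norm (the time differential
#' of acceleration) above `jerk_threshold`.
#'
#' @param time Time stamps, s.
#' @param speed Speed series for `"speed-peak"`, m s^-1.
#' @param accel High-rate acceleration matrix for `"jerk-peak"`, m s^-2.
#' @param method `"speed-peak"` or `"jerk-peak"`.
#' @param window_s Deceleration look-ahead window, s.
#' @param decel_frac Required speed drop as a fraction of the peak.
#' @param jerk_threshold Jerk-norm threshold, m s^-3 (per deployment).
#' @param min_separation_s Minimum spacing between reported lunges, s.
#' @return Ordered numeric vector of lunge times, s.
#' @export
detect_lunges <- function(time, speed = NULL, accel = NULL,
                          method = c("speed-peak", "jerk-peak"),
                          window_s = 5, decel_frac = 0.25,
                          jerk_threshold = NULL, min_separation_s = 10) {
  method <- match.arg(method)
  if (method == "speed-peak") {
    if (is.null(speed)) stop("speed-peak method needs a speed series")
    s <- speed
    mu <- mean(s, na.rm = TRUE); sd_ <- stats::sd(s, na.rm = TRUE)
    thr <- mu + 2 * sd_
    cand <- which(!is.na(s) & s > thr)
    cand <- cand[cand > 1 & cand < length(s)]
    cand <- cand[s[cand] >= s[cand - 1] & s[cand] >= s[cand + 1]]
    dt <- stats::median(diff(time))
    wn <- max(1L, round(window_s / dt))
    keep <- vapply(cand, function(i) {
      j <- seq(i + 1, min(length(s), i + wn))
      any(!is.na(s[j]) & (s[i] - s[j]) >= decel_frac * s[i])
    }, logical(1))
    times <- time[cand[keep]]
  } else {
    if (is.null(accel)) stop("jerk-peak method needs an acceleration matrix")
    accel <- as.matrix(accel)
    dt <- stats::median(diff(time))
    jerk <- sqrt(rowSums((apply(accel, 2, function(x) c(0, diff(x))) / dt)^2))
    if (is.null(jerk_threshold))
      jerk_threshold <- mean(jerk) + 3 * stats::sd(jerk)
    cand <- which(jerk > jerk_threshold)
    cand <- cand[cand > 1 & cand < length(jerk)]
    cand <- cand[jerk[cand] >= jerk[cand - 1] & jerk[cand] >= jerk[cand + 1]]
    times <- time[cand]
  }
  times <- sort(times)
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) > min_separation_s)
    times <- times[keep]
  }
  times
}

#' Preprocess a tag record into whale-frame kinematics
#'
#' Runs the full per-deployment preprocessing chain: optional pressure
#' calibration, rotation to the whale frame, low/high-frequency separation,
#' pitch and roll, decimation of acceleration-derived series to the
#' depth-channel rate (by averaging), speed determination appropriate to the
#' tag model, stroke/glide labelling, dive and dive-phase segmentation, and
#' lunge detection.
#'
#' @param record A [tag_record()].
#' @param orientation Rotation matrix or `"auto"` (see
#'   [rotate_to_whale_frame()]); `NULL` skips rotation.
#' @param cutoff_hz Low-pass cutoff for the gravity/specific split, Hz.
#' @param stroke_threshold Stroke envelope threshold, m s^-2.
#' @param pressure_calibration Optional `list(offset =, scale =)` applied
#'   first when the record has no depth channel.
#' @param lunge_method `"speed-peak"`, `"jerk-peak"` or `"none"`.
#' @param dive_threshold_m Dive definition depth, m.
#' @param min_pitch_deg Steepness floor for depth-rate speed, degrees.
#' @return An object of class `tag_kinematics`: a list with `kinematics`
#'   (data frame: time, depth, pitch, roll, speed, stroking), `glides`,
#'   `dives` (with nested phase rows), `phases`, `lunge_times`, and
#'   `settings` (every threshold actually applied, plus any speed
#'   calibration).
#' @export
preprocess_tag <- function(record,
                           orientation = NULL,
                           cutoff_hz = 0.135,
                           stroke_threshold = 0.15,
                           pressure_calibration = NULL,
                           lunge_method = c("speed-peak", "jerk-peak", "none"),
                           dive_threshold_m = 10,
                           min_pitch_deg = 30) {
  lunge_method <- match.arg(lunge_method)
  if (is.null(record$depth)) {
    if (is.null(pressure_calibration))
      stop("record has no depth channel and no pressure calibration was given")
    record <- pressure_to_depth(record, pressure_calibration$offset,
                                pressure_calibration$scale)
  }
  if (!is.null(orientation))
    record <- rotate_to_whale_frame(record, orientation)

  sep <- separate_acceleration(record$accel, record$accel_rate, cutoff_hz)
  pr <- compute_pitch_roll(sep$low)
  axes <- if (record$tag_model == "impeller-speed-tag") 1 else c(1, 3)
  st <- detect_strokes(sep$high, record$accel_time,
                       threshold = stroke_threshold, axes = axes)

  # decimate acceleration-rate series to the depth grid by averaging
  bin <- findInterval(record$accel_time,
                      c(record$time, Inf) - 0.5 / record$depth_rate)
  bin[bin < 1] <- 1L; bin[bin > length(record$time)] <- length(record$time)
  dec <- function(x) as.vector(tapply(x, bin, mean, na.rm = TRUE))[
    match(seq_along(record$time), sort(unique(bin)))]
  pitch <- dec(pr$pitch); roll <- dec(pr$roll)
  stroking <- as.vector(tapply(st$stroking, bin, any))[
    match(seq_along(record$time), sort(unique(bin)))]
  stroking[is.na(stroking)] <- TRUE  # no accel coverage: be conservative

  calibration <- NULL
  if (record$tag_model == "impeller-speed-tag") {
    cal <- calibrate_impeller_speed(record$time, record$depth, pitch,
                                    record$impeller)
    speed <- cal$speed
    calibration <- cal[c("slope", "intercept", "n_intervals")]
  } else {
    speed <- speed_from_depth_rate(record$time, record$depth, pitch,
                                   min_pitch_deg)
  }

  dives <- detect_dives(record$time, record$depth, dive_threshold_m)
  phases <- NULL
  if (nrow(dives) > 0) {
    phases <- do.call(rbind, lapply(seq_len(nrow(dives)), function(k) {
      i <- record$time >= dives$start_time[k] & record$time <= dives$end_time[k]
      ph <- segment_dive_phases(record$time[i], record$depth[i], pitch[i])
      ph$dive_id <- dives$dive_id[k]
      ph
    }))
  }

  lunge_times <- numeric()
  if (lunge_method == "speed-peak") {
    lunge_times <- detect_lunges(record$time, speed = speed,
                                 method = "speed-peak")
  } else if (lunge_method == "jerk-peak") {
    lunge_times <- detect_lunges(record$accel_time, accel = sep$high,
                                 method = "jerk-peak")
  }
  if (nrow(dives) > 0) {
    dives$lunge_count <- vapply(seq_len(nrow(dives)), function(k)
      sum(lunge_times >= dives$start_time[k] & lunge_times <= dives$end_time[k]),
      integer(1))
  }

  structure(list(
    deployment_id = record$deployment_id,
    kinematics = data.frame(time = record$time, depth = record$depth,
                            pitch = pitch, roll = roll, speed = speed,
                            stroking = stroking),
    high_freq = sep$high, low_freq = sep$low,
    accel_time = record$accel_time,
    glides = st$glides, dives = dives, phases = phases,
    lunge_times = lunge_times,
    tag_model = record$tag_model,
    settings = list(cutoff_hz = cutoff_hz,
                    stroke_threshold = stroke_threshold,
                    dive_threshold_m = dive_threshold_m,
                    min_pitch_deg = min_pitch_deg,
                    filter_order = sep$order,
                    lunge_method = lunge_method,
                    calibration = calibration)),
    class = "tag_kinematics")
}

#' @export
print.tag_kinematics <- function(x, ...) {
  cat("Whale-frame kinematics for ", x$deployment_id, "\n",
      "  ", nrow(x$kinematics), " samples; ", nrow(x$dives), " dives; ",
      nrow(x$glides), " glide intervals; ", length(x$lunge_times),
      " lunges\n", sep = "")
  invisible(x)
}
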