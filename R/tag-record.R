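#' Construct a tag record
#'
#' A `tag_record` holds the raw (or calibrated) sensor streams of one tag
#' deployment: time, pressure or depth at `depth_rate` Hz, 3-axis acceleration
#' at `accel_rate` Hz, and optionally an impeller rotation channel. Depth is in
#' metres, positive down; acceleration contains both specific (stroking) and
#' gravitational components in the tag frame, m s^-2; time is seconds from
#' deployment start.
#'
#' @param deployment_id Character scalar naming the deployment.
#' @param time Time stamps of the depth-rate channels, s, strictly increasing.
#' @param depth Depth, m (positive down), or `NULL` if only `pressure` is
#'   available.
#' @param pressure Raw pressure channel, or `NULL` if `depth` is given.
#' @param accel Numeric matrix with 3 columns (surge, sway, heave once in the
#'   whale frame), m s^-2, sampled at `accel_rate`.
#' @param accel_time Time stamps of the acceleration rows, s. Defaults to a
#'   uniform grid at `accel_rate` starting at `time[1]`.
#' @param accel_rate Acceleration sampling rate, Hz.
#' @param depth_rate Depth-channel sampling rate, Hz.
#' @param impeller Impeller rotation rate, rotations s^-1 (same grid as
#'   `time`), or `NULL`.
#' @param tag_model `"impeller-speed-tag"` (speed measured by impeller) or
#'   `"depth-rate-speed-tag"` (glide speed estimated from depth rate / sin
#'   pitch).
#' @return An object of class `tag_record`.
#' @export
tag_record <- function(deployment_id, time, depth = NULL, pressure = NULL,
                       accel, accel_time = NULL,
                       accel_rate, depth_rate,
                       impeller = NULL,
                       tag_model = c("impeller-speed-tag",
                                     "depth-rate-speed-tag")) {
  tag_model <- match.arg(tag_model)
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (is.null(depth) && is.null(pressure))
    stop("one of depth or pressure is required")
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("accel must have 3 columns")
  if (accel_rate < depth_rate)
    stop("accel_rate must be >= depth_rate")
  if (is.null(accel_time))
    accel_time <- time[1] + seq_len(nrow(accel)) / accel_rate - 1 / accel_rate
  if (length(accel_time) != nrow(accel))
    stop("accel_time length must match accel rows")
  chans <- list(time = time, depth = depth, pressure = pressure,
                impeller = impeller)
  for (nm in names(chans)) {
    x <- chans[[nm]]
    if (!is.null(x)) {
      if (length(x) != length(time))
        stop(nm, " must have the same length as time")
      if (!all(is.finite(x))) stop(nm, " contains non-finite values")
    }
  }
  if (!all(is.finite(accel))) stop("accel contains non-finite values")
  if (!is.null(depth) && any(depth < -1))
    stop("depth below -1 m after calibration; check the sign convention")
  structure(list(deployment_id = as.character(deployment_id),
                 time = time, depth = depth, pressure = pressure,
                 accel = accel, accel_time = as.numeric(accel_time),
                 accel_rate = accel_rate, depth_rate = depth_rate,
                 impeller = impeller, tag_model = tag_model),
            class = "tag_record")
}

#' @export
print.tag_record <- function(x, ...) {
  dur <- diff(range(x$time))
  cat("Tag record ", x$deployment_id, " (", x$tag_model, ")\n",
      "  duration ", round(dur / 3600, 2), " h; depth channel at ",
      x$depth_rate, " Hz; acceleration at ", x$accel_rate, " Hz\n",
      "  depth ", if (is.null(x$depth)) "not yet calibrated" else
        paste0("0-", round(max(x$depth), 1), " m"),
      "; impeller ", if (is.null(x$impeller)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Convert raw pressure to depth
#'
#' Applies an affine calibration `depth = (pressure - offset) * scale` so that
#' surface intervals read near zero metres and depth is positive down.
#'
#' @param record A [tag_record()] with a `pressure` channel.
#' @param offset Pressure reading at the surface (sensor units).
#' @param scale Metres per sensor unit; must be positive and finite.
#' @return The record with a `depth` channel added (pressure retained).
#' @examples
#' rec <- tag_record("d1", time = 0:9, pressure = rep(10, 10),
#'                   accel = matrix(rep(c(0, 0, 9.8), each = 10), ncol = 3),
#'                   accel_rate = 1, depth_rate = 1)
#' pressure_to_depth(rec, offset = 5, scale = 2)$depth
#' @export
pressure_to_depth <- function(record, offset, scale) {
  if (is.null(record$pressure)) stop("record has no pressure channel")
  if (missing(offset) || missing(scale) ||
      !is.finite(offset) || !is.finite(scale))
    stop("finite calibration offset and scale are required")
  if (scale <= 0) stop("calibration scale must be positive")
  record$depth <- (record$pressure - offset) * scale
  record
}
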