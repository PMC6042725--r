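# Extraction of 5-s sub-glides, per-glide features and observation error,
# and the inclusion filters that produce the model-ready glide table.

#' Tile glide intervals into 5-second sub-glides
#'
#' Glides shorter than `window_s` are discarded; longer glides are broken
#' into consecutive non-overlapping `window_s`-second sub-glides starting at
#' glide onset, dropping any trailing remainder.
#'
#' @param glides Data frame with `start_time` and `end_time` columns, s.
#' @param window_s Sub-glide length, s (5 by default).
#' @return Data frame with one row per sub-glide: `glide_id`, `start_time`,
#'   `end_time`.
#' @export
extract_subglides <- function(glides, window_s = 5) {
  out <- list()
  for (k in seq_len(nrow(glides))) {
    dur <- glides$end_time[k] - glides$start_time[k]
    nwin <- floor(dur / window_s)
    if (nwin < 1) next
    s <- glides$start_time[k] + (seq_len(nwin) - 1) * window_s
    out[[length(out) + 1]] <- data.frame(glide_id = k, start_time = s,
                                         end_time = s + window_s)
  }
  if (length(out) == 0)
    return(data.frame(glide_id = integer(), start_time = numeric(),
                      end_time = numeric()))
  do.call(rbind, out)
}

#' Circular variance of a set of angles
#'
#' One minus the mean resultant length of unit vectors at the given angles:
#' 0 for identical angles, 1 for angles spread uniformly around the circle.
#' Used to screen out glides with unstable roll.
#'
#' @param angles Angles in radians (`NA` dropped).
#' @return Value in \[0, 1\].
#' @examples
#' circular_variance(c(0, pi / 2))  # 1 - sqrt(2)/2
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2) return(NA_real_)
  1 - sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

#' Compute features of one sub-glide window
#'
#' Acceleration along the path is the ordinary-least-squares slope of speed
#' versus time over the window; its observation-error scale is the root mean
#' square of the regression residuals. Depth, speed and pitch are window
#' means; roll stability is the circular variance of roll. A window with
#' missing speed or acceleration anywhere, or fewer than `min_samples` valid
#' samples, is flagged invalid rather than raising an error.
#'
#' @param time,depth,speed,pitch,roll Sample series covering the window.
#' @param min_samples Minimum number of valid speed samples.
#' @return One-row data frame: `d`, `v`, `p`, `a`, `a_se`, `roll_circvar`,
#'   `n_samples`, `valid`.
#' @export
subglide_features <- function(time, depth, speed, pitch, roll,
                              min_samples = 3) {
  ok <- is.finite(speed) & is.finite(time)
  valid <- sum(ok) >= min_samples && all(is.finite(speed)) &&
    all(is.finite(pitch))
  if (sum(ok) >= min_samples) {
    tt <- time[ok] - mean(time[ok]); vv <- speed[ok]
    slope <- sum(tt * (vv - mean(vv))) / sum(tt^2)
    resid <- vv - mean(vv) - slope * tt
    a <- slope
    a_se <- sqrt(mean(resid^2))
  } else {
    a <- NA_real_; a_se <- NA_real_
  }
  data.frame(d = mean(depth, na.rm = TRUE),
             v = mean(speed, na.rm = TRUE),
             p = mean(pitch, na.rm = TRUE),
             a = a, a_se = a_se,
             roll_circvar = circular_variance(roll),
             n_samples = sum(ok),
             valid = valid)
}

#' Attach seawater density from a CTD profile
#'
#' Interpolates seawater density at each sub-glide's mean depth from a CTD
#' cast (linear in depth, constant extrapolation beyond the profile ends).
#'
#' @param table Data frame with a depth column `d` (m).
#' @param ctd_profile Data frame with columns `depth_m` and `density_kg_m3`;
#'   at least one row, densities within \[1000, 1060\].
#' @return `table` with a `rho_sw` column (kg m^-3).
#' @export
attach_seawater_density <- function(table, ctd_profile) {
  if (is.null(ctd_profile) || nrow(ctd_profile) < 1)
    stop("empty CTD profile")
  if (any(ctd_profile$density_kg_m3 < 1000 | ctd_profile$density_kg_m3 > 1060))
    stop("CTD densities outside the plausible seawater range [1000, 1060]")
  if (nrow(ctd_profile) == 1) {
    table$rho_sw <- rep(ctd_profile$density_kg_m3, nrow(table))
  } else {
    table$rho_sw <- stats::approx(ctd_profile$depth_m,
                                  ctd_profile$density_kg_m3,
                                  xout = table$d, rule = 2)$y
  }
  table
}

#' Apply the sub-glide inclusion filters
#'
#' Retains stable, steep, non-feeding sub-glides with complete data:
#' |pitch| > `min_pitch_deg`, circular variance of roll < `max_roll_circvar`,
#' more than `lunge_exclusion_s` seconds since the most recent lunge, and
#' valid features. Counts removed by each rule are recorded both
#' independently (each rule against the full table) and sequentially in the
#' order pitch, roll, missing-data, lunge.
#'
#' @param table Sub-glide table with columns `p` (radians), `roll_circvar`,
#'   `post_lunge_s`, `valid`.
#' @param min_pitch_deg Steep-pitch criterion, degrees.
#' @param max_roll_circvar Roll-stability criterion.
#' @param lunge_exclusion_s Post-lunge exclusion window, s.
#' @return A list with `retained` (the filtered table), and `audit`: total,
#'   per-rule sequential removals, per-rule independent removal fractions,
#'   and the retained fraction.
#' @export
filter_subglides <- function(table, min_pitch_deg = 30,
                             max_roll_circvar = 0.1,
                             lunge_exclusion_s = 46) {
  n0 <- nrow(table)
  fail_pitch <- !(abs(table$p) > min_pitch_deg * pi / 180)
  fail_roll <- !(is.finite(table$roll_circvar) &
                   table$roll_circvar < max_roll_circvar)
  fail_missing <- !table$valid
  fail_lunge <- !(table$post_lunge_s > lunge_exclusion_s)
  seq_keep <- rep(TRUE, n0)
  removed <- c(pitch = 0L, roll = 0L, missing = 0L, lunge = 0L)
  for (rule in c("pitch", "roll", "missing", "lunge")) {
    f <- switch(rule, pitch = fail_pitch, roll = fail_roll,
                missing = fail_missing, lunge = fail_lunge)
    removed[rule] <- sum(seq_keep & f)
    seq_keep <- seq_keep & !f
  }
  retained <- table[seq_keep, , drop = FALSE]
  audit <- list(
    total = n0,
    removed = as.list(removed),
    removed_fraction = as.list(removed / max(1L, n0)),
    independent_fraction = list(pitch = mean(fail_pitch),
                                roll = mean(fail_roll),
                                missing = mean(fail_missing),
                                lunge = mean(fail_lunge)),
    retained = nrow(retained),
    retained_fraction = nrow(retained) / max(1L, n0))
  list(retained = retained, audit = audit)
}

#' Flag deployments with too few usable sub-glides
#'
#' Deployments contributing fewer than `min_n` retained sub-glides are
#' excluded from the Bayesian estimation.
#'
#' @param table Filtered sub-glide table with a `deployment_id` column.
#' @param min_n Minimum sub-glide count (20).
#' @return Data frame with `deployment_id`, `n_glides`, `eligible`.
#' @export
check_minimum_glides <- function(table, min_n = 20) {
  counts <- table(table$deployment_id)
  data.frame(deployment_id = names(counts),
             n_glides = as.integer(counts),
             eligible = as.integer(counts) >= min_n,
             row.names = NULL)
}

#' Build the model-ready glide table from preprocessed kinematics
#'
#' Extracts 5-s sub-glides from the glide intervals of a preprocessed
#' deployment, computes per-glide features and observation error, attaches
#' seawater density from the CTD profile, applies the inclusion filters and
#' tags each sub-glide with its dive and dive phase.
#'
#' @param kin A `tag_kinematics` object from [preprocess_tag()].
#' @param ctd_profile CTD data frame (`depth_m`, `density_kg_m3`).
#' @param min_pitch_deg,max_roll_circvar,lunge_exclusion_s Filter settings,
#'   see [filter_subglides()].
#' @param window_s Sub-glide length, s.
#' @return A list of class `glide_table`: `glides` (retained rows with
#'   columns deployment_id, dive_id, phase, start_time, d, v, p, a, a_se,
#'   roll_circvar, rho_sw, post_lunge_s), `audit` (filter accounting) and
#'   `eligibility`.
#' @export
extract_glide_table <- function(kin, ctd_profile,
                                min_pitch_deg = 30, max_roll_circvar = 0.1,
                                lunge_exclusion_s = 46, window_s = 5) {
  sg <- extract_subglides(kin$glides, window_s)
  k <- kin$kinematics
  feats <- do.call(rbind, lapply(seq_len(nrow(sg)), function(i) {
    j <- k$time >= sg$start_time[i] & k$time < sg$end_time[i]
    subglide_features(k$time[j], k$depth[j], k$speed[j], k$pitch[j], k$roll[j])
  }))
  if (nrow(sg) == 0) {
    feats <- data.frame(d = numeric(), v = numeric(), p = numeric(),
                        a = numeric(), a_se = numeric(),
                        roll_circvar = numeric(), n_samples = integer(),
                        valid = logical())
  }
  tab <- cbind(sg, feats)
  tab$deployment_id <- kin$deployment_id
  # seconds since most recent lunge (Inf if none before the sub-glide)
  tab$post_lunge_s <- vapply(tab$start_time, function(s) {
    prev <- kin$lunge_times[kin$lunge_times <= s]
    if (length(prev) == 0) Inf else s - max(prev)
  }, numeric(1))
  # dive and phase membership
  tab$dive_id <- NA_integer_
  tab$phase <- NA_character_
  if (!is.null(kin$dives) && nrow(kin$dives) > 0) {
    for (i in seq_len(nrow(tab))) {
      w <- which(kin$dives$start_time <= tab$start_time[i] &
                   kin$dives$end_time >= tab$end_time[i])
      if (length(w) == 1) {
        tab$dive_id[i] <- kin$dives$dive_id[w]
        ph <- kin$phases[kin$phases$dive_id == kin$dives$dive_id[w], ]
        m <- which(ph$start_time <= tab$start_time[i] &
                     ph$end_time >= tab$start_time[i])
        if (length(m) >= 1) tab$phase[i] <- ph$phase[m[1]]
      }
    }
  }
  tab <- attach_seawater_density(tab, ctd_profile)
  filt <- filter_subglides(tab, min_pitch_deg, max_roll_circvar,
                           lunge_exclusion_s)
  glides <- filt$retained
  cols <- c("deployment_id", "dive_id", "phase", "start_time", "d", "v", "p",
            "a", "a_se", "roll_circvar", "rho_sw", "post_lunge_s")
  glides <- glides[, cols]
  structure(list(glides = glides, audit = filt$audit,
                 eligibility = check_minimum_glides(glides)),
            class = "glide_table")
}

#' @export
print.glide_table <- function(x, ...) {
  cat("Glide table: ", nrow(x$glides), " retained 5-s sub-glides of ",
      x$audit$total, " extracted (",
      round(100 * x$audit$retained_fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Read a glide table from a delimited file
#'
#' Reads a per-glide CSV in the package's exchange schema, or any external
#' layout via `column_map` (a named character vector mapping package column
#' names to file column names), e.g. a deposited supplementary per-glide
#' table.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector, names = package
#'   columns (`deployment_id`, `dive_id`, `d`, `v`, `p`, `a`, `a_se`,
#'   `rho_sw`, ...), values = file columns.
#' @return Data frame in the exchange schema.
#' @export
read_glide_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(df))
    if (length(missing_cols) > 0)
      stop("columns not found in ", path, ": ",
           paste(missing_cols, collapse = ", "))
    df <- df[, unname(column_map)]
    names(df) <- names(column_map)
  }
  need <- c("deployment_id", "d", "v", "p", "a", "a_se", "rho_sw")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("glide table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  df
}
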