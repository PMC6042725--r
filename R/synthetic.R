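# Synthetic tag data with known ground truth. The generator emulates the
# study conditions: multi-dive depth profiles with descent/bottom/ascent
# phases, stroking oscillations interleaved with glides whose speed evolves
# by integrating the force balance, lunge events, gravity-consistent
# low-frequency acceleration, and Gaussian observation noise on per-glide
# acceleration.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults reproduce the study conditions: 24 individuals; per-record mean
#' dive depths spanning 22.8-180.8 m with a 388.3 m maximum; swim speed
#' 1.5 +/- 0.4 m s^-1; descent pitch around -40 degrees and ascent pitch
#' around +30 degrees; a 1 Hz depth channel with 32 Hz acceleration;
#' acceleration observation noise 0.01 m s^-2 on 5-s sub-glides; and a
#' two-point linear CTD profile.
#'
#' @param n_whales Number of individuals.
#' @param dives_per_whale Dives per deployment.
#' @param glides_per_dive Sub-glides per dive in table simulation.
#' @param mean_depth_range Range of per-whale mean dive depths, m.
#' @param max_depth Depth cap, m.
#' @param speed_mean,speed_sd Glide speed distribution, m s^-1.
#' @param pitch_descent_deg,pitch_ascent_deg Mean (and sd) pitch by phase,
#'   degrees, as `c(mean, sd)`.
#' @param filter_safe If `TRUE`, draw pitches with magnitude in 31-70 degrees
#'   and stable roll so every generated sub-glide passes the inclusion
#'   filters by construction.
#' @param noise_sd Gaussian noise on sub-glide acceleration, m s^-2.
#' @param a_se_jitter Relative jitter on the reported per-glide error scale.
#' @param accel_rate,depth_rate Sampling rates for time-series simulation, Hz.
#' @param stroke_hz,stroke_amp Stroking oscillation frequency (Hz) and surge
#'   amplitude (m s^-2).
#' @param segment_s Length of alternating stroke/glide segments within
#'   descent and ascent, s.
#' @param ts_pitch_deg Magnitude of the descent/ascent pitch used in
#'   time-series simulation, degrees (steep enough for impeller
#'   calibration intervals).
#' @param bottom_s Bottom-phase duration, s.
#' @param surface_s Surface interval between dives, s.
#' @param lunges_per_dive Expected lunges per dive (Poisson; time-series and
#'   post-lunge planting).
#' @param glide_bias_scale Strength of the buoyancy-driven glide allocation
#'   in time-series simulation: each descent segment is a glide with
#'   probability `0.5 + scale x (rho_tissue - mean seawater density)` (and
#'   the complement on ascent), so denser whales glide relatively more on
#'   descent. 0 (default) allocates glides symmetrically.
#' @param frac_shallow_pitch,frac_unstable_roll,frac_post_lunge Fractions of
#'   table rows planted to violate each inclusion filter (for filter-audit
#'   testing).
#' @param ctd Two-column CTD data frame (`depth_m`, `density_kg_m3`).
#' @param mount_roll,mount_pitch Tag mounting orientation, radians.
#' @param impeller_slope,impeller_intercept True impeller calibration
#'   (speed = slope x rotation + intercept).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_whales = 24, dives_per_whale = 10,
                            glides_per_dive = 20,
                            mean_depth_range = c(22.8, 180.8),
                            max_depth = 388.3,
                            speed_mean = 1.5, speed_sd = 0.4,
                            pitch_descent_deg = c(-39.8, 20.6),
                            pitch_ascent_deg = c(30.6, 22.4),
                            filter_safe = TRUE,
                            noise_sd = 0.01, a_se_jitter = 0,
                            accel_rate = 32, depth_rate = 1,
                            stroke_hz = 0.5, stroke_amp = 0.3,
                            segment_s = 60, bottom_s = 60, surface_s = 60,
                            ts_pitch_deg = 60, glide_bias_scale = 0,
                            lunges_per_dive = 0,
                            frac_shallow_pitch = 0, frac_unstable_roll = 0,
                            frac_post_lunge = 0,
                            ctd = data.frame(depth_m = c(0, 400),
                                             density_kg_m3 = c(1026.0, 1027.6)),
                            mount_roll = 0, mount_pitch = 0,
                            impeller_slope = 0.35, impeller_intercept = 0.1) {
  cfg <- as.list(environment())
  stopifnot(n_whales >= 1, dives_per_whale >= 1, glides_per_dive >= 1,
            noise_sd >= 0, max_depth > 0,
            all(c(frac_shallow_pitch, frac_unstable_roll,
                  frac_post_lunge) >= 0))
  class(cfg) <- "scenario_config"
  cfg
}

#' Draw a synthetic population with known ground truth
#'
#' Per-individual tissue density and drag term, and global means/sds, drawn
#' from Normal population distributions truncated to the prior supports.
#' Per-dive gas volumes are drawn later, at table/time-series simulation,
#' from the gas-volume population parameters recorded here. Defaults are the
#' population values estimated in the study (tissue density 1031.6 kg m^-3
#' with variance 26.5; drag 11.8e-6 m^2 kg^-1 with variance 23.2e-12; gas
#' 27.7 ml kg^-1 with variance 236.5).
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; draws are reproducible.
#' @param rho_g,rho_sd Population mean and sd of surface tissue density,
#'   kg m^-3.
#' @param cdam_g,cdam_sd Population mean and sd of the drag term, m^2 kg^-1.
#' @param vair_g,vair_sd Population (dive-average) mean and sd of gas volume,
#'   ml kg^-1.
#' @param priors A [prior_spec()] supplying truncation bounds.
#' @return An object of class `synthetic_truth`: per-individual `rho` and
#'   `cdam`, the population parameters, the noise scale and the seed.
#' @export
draw_population <- function(config = scenario_config(), seed = 1,
                            rho_g = 1031.6, rho_sd = sqrt(26.5),
                            cdam_g = 11.8e-6, cdam_sd = sqrt(23.2) * 1e-6,
                            vair_g = 27.7, vair_sd = sqrt(236.5),
                            priors = prior_spec()) {
  set.seed(seed)
  trunc_mass <- function(mean, sd, lo, hi) {
    if (sd == 0) return(1)
    stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  }
  rtnorm <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                                   stats::pnorm(hi, mean, sd)), mean, sd)
    pmin(hi, pmax(lo, x))
  }
  for (m in list(c(trunc_mass(rho_g, rho_sd, priors$rho_bounds[1],
                              priors$rho_bounds[2]), "tissue density"),
                 c(trunc_mass(cdam_g, cdam_sd, priors$cdam_bounds[1],
                              priors$cdam_bounds[2]), "drag term"),
                 c(trunc_mass(vair_g, vair_sd, priors$vair_bounds[1],
                              priors$vair_bounds[2]), "gas volume")))
    if (as.numeric(m[1]) < 0.5)
      warning("population sd for ", m[2],
              " truncates more than half of the distribution")
  nw <- config$n_whales
  structure(list(
    deployment_id = sprintf("synth_%02d", seq_len(nw)),
    rho = rtnorm(nw, rho_g, rho_sd, priors$rho_bounds[1], priors$rho_bounds[2]),
    cdam = rtnorm(nw, cdam_g, cdam_sd, priors$cdam_bounds[1],
                  priors$cdam_bounds[2]),
    rho_g = rho_g, rho_sd = rho_sd, cdam_g = cdam_g, cdam_sd = cdam_sd,
    vair_g = vair_g, vair_sd = vair_sd,
    vair_bounds = priors$vair_bounds,
    noise_sd = config$noise_sd, seed = seed), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic population truth: ", length(x$rho), " individuals\n",
      "  rho ", round(x$rho_g, 1), " +/- ", round(x$rho_sd, 2),
      " kg m^-3; CdAm ", signif(x$cdam_g * 1e6, 3), "e-6 +/- ",
      signif(x$cdam_sd * 1e6, 3), "e-6 m^2 kg^-1; Vair ",
      round(x$vair_g, 1), " +/- ", round(x$vair_sd, 1), " ml kg^-1\n",
      sep = "")
  invisible(x)
}

rtnorm_one <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                                 stats::pnorm(hi, mean, sd)), mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Simulate a model-ready sub-glide table with known truth
#'
#' Draws glide states (depth, speed, pitch, phase, dive) from the scenario,
#' computes the noiseless force-balance acceleration from the individual's
#' true parameters and the dive's true gas volume, adds Gaussian noise, and
#' attaches seawater density from the scenario CTD. Optionally plants rows
#' that violate the pitch / roll-stability / post-lunge inclusion filters in
#' known proportions.
#'
#' @param truth A [draw_population()] result.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param constants [physical_constants()].
#' @return A list of class `synthetic_glides`: `glides` (table rows,
#'   including any planted violations, with `a_true` and planting flags) and
#'   `truth` (with per-dive gas volumes appended as `vair_by_dive`).
#' @export
simulate_subglide_table <- function(truth, config = scenario_config(),
                                    seed = 1,
                                    constants = physical_constants()) {
  set.seed(seed)
  nw <- length(truth$rho)
  rows <- vector("list", nw)
  vair_all <- list()
  for (w in seq_len(nw)) {
    nd <- config$dives_per_whale
    ng <- config$glides_per_dive
    mean_d <- stats::runif(1, config$mean_depth_range[1],
                           config$mean_depth_range[2])
    dive_depth <- pmin(config$max_depth,
                       pmax(12, stats::rnorm(nd, mean_d, mean_d / 3)))
    vair_d <- rtnorm_one(nd, truth$vair_g, truth$vair_sd,
                         truth$vair_bounds[1], truth$vair_bounds[2])
    vair_all[[w]] <- vair_d
    dive <- rep(seq_len(nd), each = ng)
    phase <- ifelse(stats::runif(nd * ng) < 0.5, "descent", "ascent")
    d <- stats::runif(nd * ng, 5, dive_depth[dive])
    v <- pmax(0.5, stats::rnorm(nd * ng, config$speed_mean, config$speed_sd))
    if (config$filter_safe) {
      p_mag <- stats::runif(nd * ng, 31, 70)
    } else {
      p_mag <- abs(ifelse(phase == "descent",
                          stats::rnorm(nd * ng, config$pitch_descent_deg[1],
                                       config$pitch_descent_deg[2]),
                          stats::rnorm(nd * ng, config$pitch_ascent_deg[1],
                                       config$pitch_ascent_deg[2])))
      p_mag <- pmin(p_mag, 89)
    }
    p <- ifelse(phase == "descent", -p_mag, p_mag) * pi / 180
    df <- data.frame(deployment_id = truth$deployment_id[w],
                     dive_id = dive, phase = phase, d = d, v = v, p = p)
    rows[[w]] <- df
  }
  tab <- do.call(rbind, rows)
  tab <- attach_seawater_density(tab, config$ctd)
  widx <- match(tab$deployment_id, truth$deployment_id)
  vair_glide <- mapply(function(w, dv) vair_all[[w]][dv], widx, tab$dive_id)
  tab$a_true <- glide_acceleration(truth$rho[widx], truth$cdam[widx],
                                   vair_glide, tab$d, tab$v, tab$p,
                                   tab$rho_sw, constants)
  tab$a <- tab$a_true + stats::rnorm(nrow(tab), 0, config$noise_sd)
  tab$a_se <- config$noise_sd *
    (1 + config$a_se_jitter * stats::runif(nrow(tab), -1, 1))
  tab$roll_circvar <- stats::runif(nrow(tab), 0, 0.05)
  tab$post_lunge_s <- Inf
  tab$start_time <- seq_len(nrow(tab)) * 10
  tab$valid <- TRUE
  tab$planted <- "none"
  # plant filter violations in known proportions
  n <- nrow(tab)
  free <- seq_len(n)
  plant <- function(frac, label, mutate) {
    k <- round(frac * n)
    if (k == 0) return(invisible())
    pick <- sample(free, k)
    free <<- setdiff(free, pick)
    tab[pick, ] <<- mutate(tab[pick, , drop = FALSE])
    tab$planted[pick] <<- label
  }
  plant(config$frac_shallow_pitch, "shallow_pitch", function(df) {
    df$p <- sign(df$p) * stats::runif(nrow(df), 5, 25) * pi / 180
    df
  })
  plant(config$frac_unstable_roll, "unstable_roll", function(df) {
    df$roll_circvar <- stats::runif(nrow(df), 0.5, 1)
    df
  })
  plant(config$frac_post_lunge, "post_lunge", function(df) {
    df$post_lunge_s <- stats::runif(nrow(df), 0, 45)
    df
  })
  truth$vair_by_dive <- vair_all
  structure(list(glides = tab, truth = truth, seed = seed),
            class = "synthetic_glides")
}

#' Simulate a full tag time series with annotations
#'
#' Builds one deployment's raw record: a multi-dive depth profile with
#' descent, bottom and ascent phases; pitch consistent with the phases
#' (ramped at transitions); alternating stroking and glide segments in which
#' glide speed evolves by integrating the force balance with a 0.2 s forward
#' Euler step; gravity-consistent low-frequency acceleration; stroking
#' oscillations on the surge (and dorso-ventral) axes; optional lunges
#' (speed spike followed by rapid deceleration); an impeller channel linear
#' in speed; and a known tag mounting rotation.
#'
#' @param truth A [draw_population()] result.
#' @param config A [scenario_config()].
#' @param whale Index of the individual to simulate.
#' @param seed Integer seed.
#' @param tag_model Tag type for the produced record.
#' @param constants [physical_constants()].
#' @return A list of class `synthetic_record`: `record` (a [tag_record()] in
#'   the tag frame) and `annotations` (true glide intervals, stroking flags,
#'   pitch/speed series, lunge times, dive plan, mounting rotation, impeller
#'   calibration, and the individual's true parameters).
#' @export
simulate_tag_record <- function(truth, config = scenario_config(),
                                whale = 1, seed = 1,
                                tag_model = "impeller-speed-tag",
                                constants = physical_constants()) {
  set.seed(seed + whale)
  dt <- 0.2  # integration step, s
  rho0 <- truth$rho[whale]; cdam <- truth$cdam[whale]
  nd <- config$dives_per_whale
  mean_d <- stats::runif(1, config$mean_depth_range[1],
                         config$mean_depth_range[2])
  dive_depth <- pmin(config$max_depth, pmax(15, stats::rnorm(nd, mean_d,
                                                             mean_d / 4)))
  vair_d <- rtnorm_one(nd, truth$vair_g, truth$vair_sd,
                       truth$vair_bounds[1], truth$vair_bounds[2])
  n_lunges <- stats::rpois(nd, config$lunges_per_dive)

  t_cur <- 0; depth_cur <- 0.2
  tt <- list(); dd <- list(); pp <- list(); vv <- list(); ss <- list()
  glide_iv <- list(); lunge_times <- numeric(); dive_plan <- list()
  ctd <- config$ctd
  rho_sw_at <- function(d) {
    if (nrow(ctd) < 2) rep(ctd$density_kg_m3[1], length(d))
    else stats::approx(ctd$depth_m, ctd$density_kg_m3, xout = d,
                       rule = 2)$y
  }
  seg_push <- function(n, p, v, strk, stop_depth = Inf) {
    # advance the state over n steps at pitch p; v may be a vector (glide
    # integration) or scalar (stroking); stops early at stop_depth
    if (length(v) == 1) v <- rep(v, n)
    dz <- -v * sin(p) * dt
    dseq <- pmax(depth_cur + cumsum(dz), 0.1)
    if (is.finite(stop_depth) && any(dseq >= stop_depth))
      n <- which(dseq >= stop_depth)[1]
    tseq <- t_cur + dt * seq_len(n)
    tt[[length(tt) + 1]] <<- tseq
    dd[[length(dd) + 1]] <<- dseq[seq_len(n)]
    pp[[length(pp) + 1]] <<- rep(p, n)
    vv[[length(vv) + 1]] <<- v[seq_len(n)]
    ss[[length(ss) + 1]] <<- rep(strk, n)
    t_cur <<- tseq[n]; depth_cur <<- dseq[n]
  }
  glide_seg <- function(dur, p, v0, vair, stop_depth = Inf) {
    # integrate the force balance during a glide at fixed pitch; the glide
    # ends early at the surface or at the dive's target depth
    n <- round(dur / dt)
    v <- numeric(n); vcur <- v0; dcur <- depth_cur
    used <- 0L
    for (i in seq_len(n)) {
      a <- glide_acceleration(rho0, cdam, vair, max(dcur, 0), max(vcur, 0),
                              p, rho_sw_at(dcur), constants)
      vcur <- max(0.3, vcur + a * dt)
      dcur <- dcur - vcur * sin(p) * dt
      if (dcur < 0.5) break
      v[i] <- vcur
      used <- i
      if (dcur >= stop_depth) break
    }
    if (used == 0L) return(v0)
    t0 <- t_cur
    seg_push(used, p, v[seq_len(used)], FALSE)
    glide_iv[[length(glide_iv) + 1]] <<- c(t0, t_cur)
    vcur
  }
  time_to_surface <- function(p, v) depth_cur / max(0.1, v * sin(p))
  ramp_pitch <- function(p_from, p_to, v, dur = 12) {
    # raised-cosine posture change: smooth enough that its spectral content
    # stays below the gravity/specific-acceleration filter cutoff
    n <- round(dur / dt)
    ps <- p_from + (p_to - p_from) *
      (1 - cos(pi * seq_len(n) / n)) / 2
    tseq <- t_cur + dt * seq_len(n)
    dz <- -v * sin(ps) * dt
    dseq <- pmax(depth_cur + cumsum(dz), 0.1)
    tt[[length(tt) + 1]] <<- tseq; dd[[length(dd) + 1]] <<- dseq
    pp[[length(pp) + 1]] <<- ps; vv[[length(vv) + 1]] <<- rep(v, n)
    ss[[length(ss) + 1]] <<- rep(TRUE, n)
    t_cur <<- tseq[n]; depth_cur <<- dseq[n]
  }
  v_cruise <- config$speed_mean
  p_desc <- -config$ts_pitch_deg * pi / 180
  p_asc <- config$ts_pitch_deg * pi / 180
  delta_rho <- rho0 - mean(rho_sw_at(c(0, config$mean_depth_range)))
  p_glide_desc <- min(0.9, max(0.1, 0.5 + config$glide_bias_scale * delta_rho))
  p_glide_asc <- min(0.9, max(0.1, 0.5 - config$glide_bias_scale * delta_rho))
  for (k in seq_len(nd)) {
    dive_start <- t_cur
    seg0 <- length(dd)
    seg_push(round(config$surface_s / dt), 0, 0.3, FALSE)  # quiet surfacing
    ramp_pitch(0, p_desc, v_cruise)
    # descent: stroke segments with glide segments interleaved at the
    # buoyancy-dependent rate
    vcur <- v_cruise
    while (depth_cur < dive_depth[k]) {
      seg_push(round(config$segment_s / dt), p_desc, v_cruise, TRUE,
               stop_depth = dive_depth[k])
      if (depth_cur >= dive_depth[k]) break
      if (stats::runif(1) < p_glide_desc)
        vcur <- glide_seg(config$segment_s, p_desc, v_cruise, vair_d[k],
                          stop_depth = dive_depth[k])
    }
    ramp_pitch(p_desc, 0, v_cruise)
    # bottom phase, with optional lunges (speed spike + sharp deceleration)
    nb <- round(config$bottom_s / dt)
    vbot <- rep(v_cruise, nb)
    if (n_lunges[k] > 0) {
      for (l in seq_len(n_lunges[k])) {
        c0 <- round(nb * l / (n_lunges[k] + 1))
        spike <- round(3 / dt)
        idx <- c0:min(nb, c0 + spike)
        prof <- c(seq(v_cruise, 3.2 * v_cruise, length.out = ceiling(length(idx) / 2)),
                  seq(3.2 * v_cruise, 0.8 * v_cruise,
                      length.out = floor(length(idx) / 2)))
        vbot[idx] <- prof[seq_along(idx)]
        lunge_times <- c(lunge_times,
                         t_cur + dt * (c0 + ceiling(length(idx) / 2)))
      }
    }
    seg_push(nb, 0, 1, TRUE); vv[[length(vv)]] <- vbot
    ramp_pitch(0, p_asc, v_cruise)
    # ascent: glide segments at the complementary rate until near surface
    while (depth_cur > 2) {
      if (stats::runif(1) < p_glide_asc) {
        vcur <- glide_seg(config$segment_s, p_asc, v_cruise, vair_d[k])
        if (depth_cur <= 2) break
      }
      n_asc <- min(round(config$segment_s / dt),
                   max(1L, floor(time_to_surface(p_asc, v_cruise) / dt)))
      seg_push(n_asc, p_asc, v_cruise, TRUE)
    }
    ramp_pitch(p_asc, 0, v_cruise)
    dive_plan[[k]] <- data.frame(
      dive = k, start = dive_start, end = t_cur,
      depth = max(unlist(dd[(seg0 + 1):length(dd)])),  # realized max depth
      target_depth = dive_depth[k], vair = vair_d[k])
  }
  seg_push(round(config$surface_s / dt), 0, 0.3, FALSE)

  time_f <- unlist(tt); depth_f <- unlist(dd); pitch_f <- unlist(pp)
  speed_f <- unlist(vv); strk_f <- unlist(ss)

  # resample onto the tag's grids
  t_end <- max(time_f)
  t_depth <- seq(0, t_end, by = 1 / config$depth_rate)
  t_acc <- seq(0, t_end, by = 1 / config$accel_rate)
  at <- function(x, tq) stats::approx(time_f, x, xout = tq, rule = 2)$y
  depth_dr <- at(depth_f, t_depth)
  speed_dr <- at(speed_f, t_depth)
  pitch_acc <- at(pitch_f, t_acc)
  strk_acc <- at(as.numeric(strk_f), t_acc) > 0.5
  g <- constants$g
  low <- cbind(g * sin(pitch_acc), 0, g * cos(pitch_acc))
  ph <- stats::runif(1, 0, 2 * pi)
  osc <- sin(2 * pi * config$stroke_hz * t_acc + ph)
  high <- cbind(config$stroke_amp * osc * strk_acc,
                0,
                0.6 * config$stroke_amp * osc * strk_acc)
  accel_whale <- low + high +
    matrix(stats::rnorm(length(t_acc) * 3, 0, 0.005), ncol = 3)
  Rm <- rotation_matrix(roll = config$mount_roll, pitch = config$mount_pitch)
  accel_tag <- accel_whale %*% Rm  # == t(t(Rm) %*% t(a)); tag = R^T whale
  impeller <- pmax(0, (speed_dr - config$impeller_intercept) /
                     config$impeller_slope +
                     stats::rnorm(length(t_depth), 0, 0.02))
  rec <- tag_record(deployment_id = truth$deployment_id[whale],
                    time = t_depth, depth = depth_dr,
                    accel = accel_tag, accel_time = t_acc,
                    accel_rate = config$accel_rate,
                    depth_rate = config$depth_rate,
                    impeller = if (tag_model == "impeller-speed-tag")
                      impeller else NULL,
                    tag_model = tag_model)
  gi <- do.call(rbind, lapply(glide_iv, function(x)
    data.frame(start_time = x[1], end_time = x[2])))
  structure(list(
    record = rec,
    annotations = list(
      glides = gi, stroking = strk_acc, accel_time = t_acc,
      pitch = pitch_acc, speed = speed_dr, depth = depth_dr,
      time = t_depth, lunge_times = lunge_times,
      dive_plan = do.call(rbind, dive_plan),
      mounting = Rm,
      impeller_calibration = c(slope = config$impeller_slope,
                               intercept = config$impeller_intercept),
      rho = truth$rho[whale], cdam = truth$cdam[whale],
      vair_by_dive = vair_d)),
    class = "synthetic_record")
}
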