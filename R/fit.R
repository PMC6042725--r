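# Hierarchical Bayesian estimation of tissue density, combined drag term and
# diving gas volume from the 5-s sub-glide table. The observation model
# treats measured glide acceleration as Normal around the force-balance
# prediction with a per-glide error scale (RMS regression residual + 0.001).
# Sampling is Gibbs via JAGS; model code is generated per structure below.

#' Define one model structure
#'
#' Each of the three unknowns can vary at different levels: tissue density
#' and drag term globally or per individual; diving gas volume globally, per
#' individual, or dive-by-dive. The 2 x 2 x 3 grid gives 12 structures.
#'
#' @param rho_level `"global"` or `"individual"`.
#' @param cdam_level `"global"` or `"individual"`.
#' @param vair_level `"global"`, `"individual"` or `"dive"`.
#' @return An object of class `model_structure`.
#' @export
model_structure <- function(rho_level = c("global", "individual"),
                            cdam_level = c("global", "individual"),
                            vair_level = c("global", "individual", "dive")) {
  s <- list(rho_level = match.arg(rho_level),
            cdam_level = match.arg(cdam_level),
            vair_level = match.arg(vair_level))
  class(s) <- "model_structure"
  s
}

#' @export
format.model_structure <- function(x, ...) {
  code <- function(l) c(global = "G", individual = "I", dive = "D")[[l]]
  paste0(code(x$rho_level), code(x$cdam_level), code(x$vair_level))
}

#' @export
print.model_structure <- function(x, ...) {
  cat("Model structure ", format(x), " (rho: ", x$rho_level,
      ", CdAm: ", x$cdam_level, ", Vair: ", x$vair_level, ")\n", sep = "")
  invisible(x)
}

#' All twelve model structures
#'
#' @return A list of [model_structure()] objects covering the full
#'   2 x 2 x 3 grid.
#' @export
all_model_structures <- function() {
  out <- list()
  for (r in c("global", "individual"))
    for (c_ in c("global", "individual"))
      for (v in c("global", "individual", "dive"))
        out[[length(out) + 1]] <- model_structure(r, c_, v)
  out
}

n_hierarchical_levels <- function(s) {
  sum(s$rho_level != "global", s$cdam_level != "global",
      s$vair_level != "global")
}

#' Prior specification
#'
#' Defaults follow the published analysis: a non-informative uniform prior
#' 800-1200 kg m^-3 for tissue density; a Normal(7e-6, 2e-6) prior truncated
#' to \[1e-6, 20e-6\] m^2 kg^-1 for the combined drag term (built from a
#' fin-whale drag coefficient and humpback allometry); a uniform prior
#' 5-80 ml kg^-1 for diving gas volume bracketing allometric total lung
#' capacity. Group-level spreads of hierarchical parameters get half-uniform
#' priors. `drag_prior = "wide"` is the sensitivity preset replacing the
#' informative drag prior by uniform 1e-6 to 40e-6 m^2 kg^-1.
#'
#' @param rho_bounds Tissue-density prior support, kg m^-3.
#' @param cdam_mean,cdam_sd,cdam_bounds Drag-term prior (m^2 kg^-1).
#' @param vair_bounds Gas-volume prior support, ml kg^-1.
#' @param sd_rho_max,sd_cdam_max,sd_vair_max Upper bounds of the uniform
#'   hyperpriors on group standard deviations (kg m^-3, m^2 kg^-1, ml kg^-1).
#' @param drag_prior `"informative"` (default) or `"wide"`.
#' @param error_increment Increment added to each per-glide error scale to
#'   keep precisions finite, m s^-2.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(rho_bounds = c(800, 1200),
                       cdam_mean = 7e-6, cdam_sd = 2e-6,
                       cdam_bounds = c(1e-6, 20e-6),
                       vair_bounds = c(5, 80),
                       sd_rho_max = 50, sd_cdam_max = 10e-6, sd_vair_max = 40,
                       drag_prior = c("informative", "wide"),
                       error_increment = 0.001) {
  drag_prior <- match.arg(drag_prior)
  if (drag_prior == "wide") cdam_bounds <- c(1e-6, 40e-6)
  structure(list(rho_bounds = rho_bounds, cdam_mean = cdam_mean,
                 cdam_sd = cdam_sd, cdam_bounds = cdam_bounds,
                 vair_bounds = vair_bounds, sd_rho_max = sd_rho_max,
                 sd_cdam_max = sd_cdam_max, sd_vair_max = sd_vair_max,
                 drag_prior = drag_prior, error_increment = error_increment),
            class = "prior_spec")
}

# JAGS model code for one structure. cdam is handled on the 1e-6 m^2 kg^-1
# scale inside the sampler for conditioning; rho in kg m^-3, vair in ml kg^-1.
build_jags_model <- function(structure, priors, fixed = character()) {
  rho_j <- switch(structure$rho_level, global = "rho.g", individual = "rho[w[j]]")
  cdam_j <- switch(structure$cdam_level, global = "cdam.g",
                   individual = "cdam[w[j]]")
  vair_j <- switch(structure$vair_level, global = "vair.g",
                   individual = "vair[w[j]]", dive = "vair[dv[j]]")
  cb <- priors$cdam_bounds * 1e6
  cdam_prior <- if (priors$drag_prior == "wide")
    sprintf("dunif(%g, %g)", cb[1], cb[2])
  else
    sprintf("dnorm(%g, %g) T(%g, %g)", priors$cdam_mean * 1e6,
            (priors$cdam_sd * 1e6)^-2, cb[1], cb[2])
  rb <- priors$rho_bounds; vb <- priors$vair_bounds
  blocks <- character()
  if (!("rho" %in% fixed)) {
    blocks <- c(blocks, sprintf("  rho.g ~ dunif(%g, %g)", rb[1], rb[2]))
    if (structure$rho_level == "individual")
      blocks <- c(blocks,
        sprintf("  rho.sd ~ dunif(1.0E-3, %g)", priors$sd_rho_max),
        sprintf(paste0("  for (i in 1:NW) { rho[i] ~ dnorm(rho.g, ",
                       "pow(rho.sd, -2)) T(%g, %g) }"), rb[1], rb[2]))
  }
  if (!("cdam" %in% fixed)) {
    blocks <- c(blocks, paste0("  cdam.g ~ ", cdam_prior))
    if (structure$cdam_level == "individual")
      blocks <- c(blocks,
        sprintf("  cdam.sd ~ dunif(1.0E-3, %g)", priors$sd_cdam_max * 1e6),
        sprintf(paste0("  for (i in 1:NW) { cdam[i] ~ dnorm(cdam.g, ",
                       "pow(cdam.sd, -2)) T(%g, %g) }"), cb[1], cb[2]))
  }
  if (!("vair" %in% fixed)) {
    blocks <- c(blocks, sprintf("  vair.g ~ dunif(%g, %g)", vb[1], vb[2]))
    if (structure$vair_level != "global") {
      idx <- if (structure$vair_level == "individual") "NW" else "ND"
      blocks <- c(blocks,
        sprintf("  vair.sd ~ dunif(1.0E-3, %g)", priors$sd_vair_max),
        sprintf(paste0("  for (k in 1:%s) { vair[k] ~ dnorm(vair.g, ",
                       "pow(vair.sd, -2)) T(%g, %g) }"), idx, vb[1], vb[2]))
    }
  }
  paste0(
    "model {\n",
    "  for (j in 1:N) {\n",
    "    mu[j] <- -0.5 * ", cdam_j, " * 1.0E-6 * rho_sw[j] * v2[j]\n",
    "      + (rho_sw[j] * (1 - r * press[j] * 101325 * 1.0E-9) / ", rho_j,
    " - 1) * g * sinp[j]\n",
    "      + ", vair_j, " * 1.0E-6 * g * sinp[j] * (rho_sw[j] - rho_air * ",
    "press[j]) / press[j]\n",
    "    a[j] ~ dnorm(mu[j], tau[j])\n",
    "  }\n",
    paste(blocks, collapse = "\n"), "\n",
    "}\n")
}

# index maps and data list for JAGS
assemble_fit_data <- function(glides, priors, constants) {
  need <- c("deployment_id", "d", "v", "p", "a", "a_se", "rho_sw")
  stopifnot(all(need %in% names(glides)))
  if (!all(vapply(glides[c("d", "v", "p", "a", "a_se", "rho_sw")],
                  function(x) all(is.finite(x)), logical(1))))
    stop("glide table contains non-finite values in d/v/p/a/a_se/rho_sw")
  whale <- factor(glides$deployment_id)
  if (is.null(glides$dive_id)) glides$dive_id <- 1L
  dive <- factor(paste(glides$deployment_id, glides$dive_id, sep = "::"))
  list(data = list(
         N = nrow(glides), NW = nlevels(whale), ND = nlevels(dive),
         w = as.integer(whale), dv = as.integer(dive),
         press = 1 + 0.1 * glides$d, v2 = glides$v^2,
         sinp = sin(glides$p), rho_sw = glides$rho_sw, a = glides$a,
         tau = (glides$a_se + priors$error_increment)^-2,
         r = constants$r, g = constants$g,
         rho_air = constants$rho_air_surface),
       whale_levels = levels(whale), dive_levels = levels(dive))
}

# over-dispersed initial values drawn from the priors (global levels only;
# JAGS draws the hierarchical nodes from their group distributions)
draw_inits <- function(structure, priors, n_chains, seed, fixed) {
  lapply(seq_len(n_chains), function(ch) {
    set.seed(seed + 1000L * ch)
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = seed + ch)
    if (!("rho" %in% fixed))
      ini$rho.g <- stats::runif(1, priors$rho_bounds[1], priors$rho_bounds[2])
    if (!("cdam" %in% fixed)) {
      cb <- priors$cdam_bounds * 1e6
      ini$cdam.g <- stats::runif(1, cb[1], cb[2])
    }
    if (!("vair" %in% fixed))
      ini$vair.g <- stats::runif(1, priors$vair_bounds[1],
                                 priors$vair_bounds[2])
    ini
  })
}

#' Fit the glide force-balance model by Gibbs sampling
#'
#' Assembles the observation model for one [model_structure()] -- measured
#' glide acceleration Normal around the force-balance prediction, with
#' per-glide precision `1 / (a_se + 0.001)^2` -- and samples the posterior in
#' independent chains with over-dispersed prior-drawn initial values. The
#' default schedule matches the published analysis: 3 chains of 24000
#' iterations, the first 12000 discarded as burn-in (after adaptation) and
#' the remainder thinned by 36.
#'
#' @param glides Glide table data frame (`deployment_id`, `dive_id`, `d`,
#'   `v`, `p`, `a`, `a_se`, `rho_sw`), or a `glide_table` object.
#' @param structure A [model_structure()].
#' @param priors A [prior_spec()].
#' @param n_chains,n_iter,burn_in,thin MCMC schedule; retained draws per
#'   chain are `(n_iter - burn_in) / thin`.
#' @param n_adapt Adaptation iterations before burn-in.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param fixed Named list fixing parameters at known values instead of
#'   sampling them, e.g. `list(cdam = 11.8e-6, vair = 28)` (`cdam` in
#'   m^2 kg^-1, `vair` in ml kg^-1, `rho` in kg m^-3). Fixed parameters must
#'   be at the global level in `structure`.
#' @param min_glides Deployments with fewer retained sub-glides are dropped
#'   before fitting.
#' @param constants [physical_constants()].
#' @param init_retries Retry cap for initialization failures.
#' @param monitor `"all"` (every sampled parameter, required for DIC and
#'   per-individual summaries) or `"global"` (only global means and group
#'   sds, lighter for large hierarchical fits).
#' @param dic Compute the deviance information criterion (needs
#'   `monitor = "all"`).
#' @return An object of class `glide_fit`: posterior samples
#'   (`coda::mcmc.list`), DIC components, per-parameter potential scale
#'   reduction, summaries and the resolved configuration.
#' @export
fit_glide_model <- function(glides, structure = model_structure(),
                            priors = prior_spec(),
                            n_chains = 3, n_iter = 24000, burn_in = 12000,
                            thin = 36, n_adapt = 500, seed = 1,
                            fixed = list(), min_glides = 20,
                            constants = physical_constants(),
                            init_retries = 100,
                            monitor = c("all", "global"), dic = TRUE) {
  monitor <- match.arg(monitor)
  if (dic && monitor != "all")
    stop("DIC needs monitor = \"all\"; set dic = FALSE for global-only ",
         "monitoring")
  if (inherits(glides, "glide_table")) glides <- glides$glides
  elig <- check_minimum_glides(glides, min_glides)
  drop <- elig$deployment_id[!elig$eligible]
  if (length(drop) > 0)
    glides <- glides[!(glides$deployment_id %in% drop), , drop = FALSE]
  if (nrow(glides) == 0) stop("no eligible deployments to fit")
  fixed_names <- names(fixed)
  for (nm in fixed_names) {
    lvl <- switch(nm, rho = structure$rho_level, cdam = structure$cdam_level,
                  vair = structure$vair_level,
                  stop("unknown fixed parameter: ", nm))
    if (lvl != "global") stop("fixed parameter ", nm, " must be global")
  }
  asm <- assemble_fit_data(glides, priors, constants)
  dat <- asm$data
  if ("rho" %in% fixed_names) dat$rho.g <- fixed$rho
  if ("cdam" %in% fixed_names) dat$cdam.g <- fixed$cdam * 1e6
  if ("vair" %in% fixed_names) dat$vair.g <- fixed$vair
  uses_w <- structure$rho_level == "individual" ||
    structure$cdam_level == "individual" ||
    structure$vair_level == "individual"
  uses_dv <- structure$vair_level == "dive"
  dat_jags <- dat
  if (!uses_w) dat_jags$w <- dat_jags$NW <- NULL
  if (!uses_dv) dat_jags$dv <- dat_jags$ND <- NULL
  code <- build_jags_model(structure, priors, fixed_names)

  monitors <- character()
  if (!("rho" %in% fixed_names)) monitors <- c(monitors, "rho.g")
  if (!("cdam" %in% fixed_names)) monitors <- c(monitors, "cdam.g")
  if (!("vair" %in% fixed_names)) monitors <- c(monitors, "vair.g")
  if (structure$rho_level == "individual")
    monitors <- c(monitors, if (monitor == "all") "rho", "rho.sd")
  if (structure$cdam_level == "individual")
    monitors <- c(monitors, if (monitor == "all") "cdam", "cdam.sd")
  if (structure$vair_level != "global")
    monitors <- c(monitors, if (monitor == "all") "vair", "vair.sd")

  jm <- NULL
  for (attempt in seq_len(init_retries)) {
    inits <- draw_inits(structure, priors, n_chains,
                        seed + (attempt - 1L) * 7919L, fixed_names)
    jm <- tryCatch(
      rjags::jags.model(textConnection(code), data = dat_jags, inits = inits,
                        n.chains = n_chains, n.adapt = n_adapt, quiet = TRUE),
      error = function(e) e)
    if (!inherits(jm, "error")) break
  }
  if (inherits(jm, "error"))
    stop("model initialization failed after ", init_retries, " attempts: ",
         conditionMessage(jm))
  if (length(monitors) > 0) {
    if (burn_in > 0) stats::update(jm, burn_in, progress.bar = "none")
    samples <- rjags::coda.samples(jm, monitors, n.iter = n_iter - burn_in,
                                   thin = thin, progress.bar = "none")
  } else {
    samples <- NULL  # every parameter fixed: nothing to sample
  }

  fit <- structure(list(
    structure = structure, priors = priors, samples = samples,
    monitors = monitors, fixed = fixed,
    data = dat, glides = glides,
    whale_levels = asm$whale_levels, dive_levels = asm$dive_levels,
    schedule = list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                    thin = thin, n_adapt = n_adapt, seed = seed),
    constants = constants), class = "glide_fit")
  fit$dic <- if (dic) compute_dic(fit) else
    list(dic = NA_real_, pd = NA_real_, dbar = NA_real_, dhat = NA_real_)
  fit$psrf <- if (is.null(samples)) NULL else
    tryCatch(gelman_rubin(samples), error = function(e) NULL)
  fit$summaries <- summarize_posterior(fit)
  fit
}

#' @export
print.glide_fit <- function(x, ...) {
  cat("Glide force-balance fit, structure ", format(x$structure), "\n",
      "  ", x$data$N, " sub-glides, ", x$data$NW, " individuals, ",
      x$data$ND, " dives\n",
      "  DIC ", round(x$dic$dic, 1), " (pD ", round(x$dic$pd, 1), ")\n",
      sep = "")
  g <- x$summaries$global
  if (!is.null(g)) print(g, row.names = FALSE, digits = 5)
  invisible(x)
}

# per-glide column lookup into the draw matrix for each parameter; NULL
# entry means the parameter is fixed and fixed_value is used instead
mu_column_map <- function(fit, cols) {
  s <- fit$structure
  one <- function(base, level, idx) {
    if (!is.null(fit$fixed[[base]]))
      return(list(cols = NULL,
                  value = switch(base, rho = fit$fixed$rho,
                                 cdam = fit$fixed$cdam * 1e6,
                                 vair = fit$fixed$vair)))
    nm <- if (level == "global") rep(paste0(base, ".g"), fit$data$N)
    else paste0(base, "[", idx, "]")
    j <- match(nm, cols)
    if (anyNA(j))
      stop("draws lack the ", base, " columns needed to evaluate the ",
           "likelihood (monitor = \"all\" is required)")
    list(cols = j, value = NULL)
  }
  list(rho = one("rho", s$rho_level, fit$data$w),
       cdam = one("cdam", s$cdam_level, fit$data$w),
       vair = one("vair", s$vair_level,
                  if (s$vair_level == "dive") fit$data$dv else fit$data$w))
}

# per-glide mean prediction from one draw (numeric row of the draw matrix)
predict_mu <- function(fit, draw, map) {
  dat <- fit$data
  pick <- function(m) if (is.null(m$cols)) m$value else draw[m$cols]
  rho <- pick(map$rho); cdam <- pick(map$cdam); vair <- pick(map$vair)
  -0.5 * cdam * 1e-6 * dat$rho_sw * dat$v2 +
    (dat$rho_sw * (1 - dat$r * dat$press * 101325 * 1e-9) / rho - 1) *
      dat$g * dat$sinp +
    vair * 1e-6 * dat$g * dat$sinp *
      (dat$rho_sw - dat$rho_air * dat$press) / dat$press
}

#' Deviance information criterion of a fitted model
#'
#' Classic DIC: the posterior-mean deviance plus the effective number of
#' parameters `pD = Dbar - D(theta_bar)`, with `theta_bar` the posterior mean
#' of every sampled parameter. A lower DIC indicates better fit relative to
#' complexity. `pd_method = "half-var"` switches to the variance-based
#' alternative `pV = var(D) / 2` for sensitivity checks.
#'
#' @param fit A `glide_fit`.
#' @param pd_method `"classic"` or `"half-var"`.
#' @return List with `dic`, `pd`, `dbar` (posterior-mean deviance) and
#'   `dhat` (deviance at the posterior mean).
#' @export
compute_dic <- function(fit, pd_method = c("classic", "half-var")) {
  pd_method <- match.arg(pd_method)
  draws <- if (is.null(fit$samples)) matrix(numeric(0), nrow = 1, ncol = 0)
  else as.matrix(fit$samples)
  dat <- fit$data
  sd_obs <- dat$tau^-0.5
  map <- mu_column_map(fit, colnames(draws))
  log_norm <- -0.5 * log(2 * pi) - log(sd_obs)
  dev_one <- function(draw) {
    mu <- predict_mu(fit, draw, map)
    -2 * sum(log_norm - 0.5 * ((dat$a - mu) / sd_obs)^2)
  }
  devs <- vapply(seq_len(nrow(draws)), function(r) dev_one(draws[r, ]),
                 numeric(1))
  if (any(!is.finite(devs)))
    stop("non-finite deviance at draws: ",
         paste(utils::head(which(!is.finite(devs))), collapse = ", "))
  dbar <- mean(devs)
  dhat <- dev_one(colMeans(draws))
  pd <- if (pd_method == "classic") dbar - dhat else stats::var(devs) / 2
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter across chains; values near
#' 1 indicate the chains have mixed, values above `flag_above` are flagged.
#'
#' @param samples A `coda::mcmc.list` with at least two chains of at least 10
#'   retained draws, or a `glide_fit`.
#' @param flag_above Flag threshold (1.1).
#' @return Data frame with `parameter`, `psrf`, `flagged`.
#' @export
gelman_rubin <- function(samples, flag_above = 1.1) {
  if (inherits(samples, "glide_fit")) samples <- samples$samples
  if (coda::nchain(samples) < 2)
    stop("potential scale reduction needs at least 2 chains")
  if (coda::niter(samples) < 10)
    stop("potential scale reduction needs at least 10 retained draws")
  gd <- coda::gelman.diag(samples, autoburnin = FALSE, multivariate = FALSE)
  data.frame(parameter = rownames(gd$psrf),
             psrf = gd$psrf[, 1],
             flagged = gd$psrf[, 1] > flag_above,
             row.names = NULL)
}

#' Posterior summaries of a fitted model
#'
#' Posterior mean and central 95 percent credible interval per parameter,
#' arranged as a global table (one row per global parameter or group
#' variance) and, when the structure includes individual variation, a
#' per-individual table. Drag terms are reported in m^2 kg^-1 (rescaled from
#' the sampler's 1e-6 conditioning scale); group `.var` entries are the
#' posterior mean of the squared group standard deviation.
#'
#' @param fit A `glide_fit`.
#' @param prob Credible-interval mass.
#' @return List with data frames `global` and (possibly `NULL`)
#'   `individuals`.
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  if (is.null(fit$samples))
    return(list(global = NULL, individuals = NULL))
  draws <- as.matrix(fit$samples)
  alpha <- (1 - prob) / 2
  scale_of <- function(nm) if (grepl("^cdam", nm)) 1e-6 else 1
  summ <- function(x, sc = 1) c(mean = mean(x) * sc,
                                lower = unname(stats::quantile(x, alpha)) * sc,
                                upper = unname(stats::quantile(x, 1 - alpha)) * sc)
  global_rows <- list()
  for (base in c("rho", "cdam", "vair")) {
    gnm <- paste0(base, ".g"); snm <- paste0(base, ".sd")
    if (gnm %in% colnames(draws)) {
      s <- summ(draws[, gnm], scale_of(gnm))
      global_rows[[paste0(base, ".g")]] <-
        data.frame(parameter = paste0(base, ".g"), mean = s["mean"],
                   lower = s["lower"], upper = s["upper"])
    }
    if (snm %in% colnames(draws)) {
      v <- (draws[, snm] * scale_of(snm))^2
      s <- summ(v)
      global_rows[[paste0(base, ".var")]] <-
        data.frame(parameter = paste0(base, ".var"), mean = s["mean"],
                   lower = s["lower"], upper = s["upper"])
    }
  }
  global <- do.call(rbind, global_rows)
  rownames(global) <- NULL

  individuals <- NULL
  if (fit$structure$rho_level == "individual" ||
      fit$structure$cdam_level == "individual") {
    nw <- fit$data$NW
    individuals <- data.frame(deployment_id = fit$whale_levels)
    for (base in c("rho", "cdam")) {
      lvl <- if (base == "rho") fit$structure$rho_level else
        fit$structure$cdam_level
      if (lvl != "individual") next
      cols <- paste0(base, "[", seq_len(nw), "]")
      if (!all(cols %in% colnames(draws))) next  # global-only monitoring
      m <- draws[, cols, drop = FALSE] * scale_of(base)
      individuals[[paste0(base, "_mean")]] <- colMeans(m)
      individuals[[paste0(base, "_lower")]] <-
        apply(m, 2, stats::quantile, alpha)
      individuals[[paste0(base, "_upper")]] <-
        apply(m, 2, stats::quantile, 1 - alpha)
    }
  }
  list(global = global, individuals = individuals)
}

#' Fit all twelve model structures and rank them by DIC
#'
#' Fits every structure in the 2 x 2 x 3 grid with a common schedule and
#' seed, ranks the results by DIC (ascending; ties broken by fewer
#' hierarchical levels), and reports the DIC gap to the runner-up. A
#' structure whose sampler fails is kept in the output with `converged =
#' FALSE` and no DIC; ranking proceeds on the remainder.
#'
#' @inheritParams fit_glide_model
#' @param structures List of structures (default all 12).
#' @param ... Passed to [fit_glide_model()] (schedule, priors, ...).
#' @return An object of class `structure_ranking`: list with `fits` (in
#'   ranked order), `table` (structure, dic, pd, max_psrf, converged) and
#'   `dic_gap`.
#' @export
fit_all_structures <- function(glides, structures = all_model_structures(),
                               seed = 1, ...) {
  fits <- vector("list", length(structures))
  rows <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    f <- tryCatch(fit_glide_model(glides, s, seed = seed, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(structure = format(s), dic = NA_real_,
                              pd = NA_real_, max_psrf = NA_real_,
                              converged = FALSE, levels = n_hierarchical_levels(s))
      fits[[i]] <- NULL
    } else {
      mp <- if (is.null(f$psrf)) NA_real_ else max(f$psrf$psrf, na.rm = TRUE)
      rows[[i]] <- data.frame(structure = format(s), dic = f$dic$dic,
                              pd = f$dic$pd, max_psrf = mp,
                              converged = is.finite(f$dic$dic),
                              levels = n_hierarchical_levels(s))
      fits[[i]] <- f
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(!tab$converged, tab$dic, tab$levels)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  fits <- fits[ord]
  dics <- tab$dic[tab$converged]
  dic_gap <- if (length(dics) >= 2) dics[2] - dics[1] else NA_real_
  structure(list(fits = fits, table = tab, dic_gap = dic_gap),
            class = "structure_ranking")
}

#' @export
print.structure_ranking <- function(x, ...) {
  cat("Model-structure ranking by DIC (best first):\n")
  print(x$table[, c("rank", "structure", "dic", "pd", "max_psrf", "converged")],
        row.names = FALSE, digits = 6)
  if (is.finite(x$dic_gap))
    cat("DIC gap to runner-up:", round(x$dic_gap, 1), "\n")
  invisible(x)
}
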