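# Summary outputs: dive statistics, glide-asymmetry versus relative tissue
# density, and the end-to-end pipeline orchestrator.

#' Per-deployment dive statistics
#'
#' Summarises a preprocessed deployment in the shape of a dive-statistics
#' table: dive count, dive duration/depth/speed (mean +/- sd), and per-phase
#' (descent, ascent) duration, pitch and percent time gliding. Percent time
#' gliding in a phase is non-stroking seconds divided by phase seconds x 100.
#'
#' @param kin A `tag_kinematics` object from [preprocess_tag()].
#' @return A one-row data frame of summaries.
#' @export
compute_dive_statistics <- function(kin) {
  k <- kin$kinematics
  dv <- kin$dives
  out <- data.frame(deployment_id = kin$deployment_id,
                    n_dives = nrow(dv))
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  if (nrow(dv) == 0) {
    for (col in c("dive_duration_mean", "dive_duration_sd", "dive_depth_mean",
                  "dive_depth_sd", "dive_speed_mean", "dive_speed_sd",
                  "descent_duration_mean", "descent_duration_sd",
                  "descent_pitch_mean", "descent_pitch_sd",
                  "descent_pct_gliding", "ascent_duration_mean",
                  "ascent_duration_sd", "ascent_pitch_mean",
                  "ascent_pitch_sd", "ascent_pct_gliding"))
      out[[col]] <- NA_real_
    return(out)
  }
  dur <- dv$end_time - dv$start_time
  out$dive_duration_mean <- mean(dur); out$dive_duration_sd <- stats::sd(dur)
  out$dive_depth_mean <- mean(dv$max_depth)
  out$dive_depth_sd <- stats::sd(dv$max_depth)
  in_dive <- rep(FALSE, nrow(k))
  for (i in seq_len(nrow(dv)))
    in_dive <- in_dive | (k$time >= dv$start_time[i] & k$time <= dv$end_time[i])
  sp <- msd(k$speed[in_dive])
  out$dive_speed_mean <- sp["mean"]; out$dive_speed_sd <- sp["sd"]
  for (phz in c("descent", "ascent")) {
    ph <- kin$phases[kin$phases$phase == phz, , drop = FALSE]
    pdur <- ph$end_time - ph$start_time
    out[[paste0(phz, "_duration_mean")]] <- mean(pdur)
    out[[paste0(phz, "_duration_sd")]] <- stats::sd(pdur)
    sel <- rep(FALSE, nrow(k))
    for (i in seq_len(nrow(ph)))
      sel <- sel | (k$time >= ph$start_time[i] & k$time <= ph$end_time[i])
    pit <- msd(k$pitch[sel] * 180 / pi)
    out[[paste0(phz, "_pitch_mean")]] <- pit["mean"]
    out[[paste0(phz, "_pitch_sd")]] <- pit["sd"]
    out[[paste0(phz, "_pct_gliding")]] <-
      if (any(sel)) 100 * mean(!k$stroking[sel], na.rm = TRUE) else NA_real_
  }
  rownames(out) <- NULL
  out
}

# percent time gliding by phase for one deployment, non-feeding dives only
phase_glide_pct <- function(kin, feeding = FALSE) {
  dv <- kin$dives
  if (nrow(dv) == 0) return(c(descent = NA_real_, ascent = NA_real_))
  if (!is.null(dv$lunge_count)) {
    dv <- if (feeding) dv[dv$lunge_count > 0, , drop = FALSE]
    else dv[dv$lunge_count == 0, , drop = FALSE]
  }
  if (nrow(dv) == 0) return(c(descent = NA_real_, ascent = NA_real_))
  k <- kin$kinematics
  res <- c(descent = NA_real_, ascent = NA_real_)
  for (phz in c("descent", "ascent")) {
    ph <- kin$phases[kin$phases$phase == phz &
                       kin$phases$dive_id %in% dv$dive_id, , drop = FALSE]
    sel <- rep(FALSE, nrow(k))
    for (i in seq_len(nrow(ph)))
      sel <- sel | (k$time >= ph$start_time[i] & k$time <= ph$end_time[i])
    if (any(sel)) res[phz] <- 100 * mean(!k$stroking[sel], na.rm = TRUE)
  }
  res
}

#' Spearman rank correlation with small-sample permutation p-value
#'
#' Large-sample approximation for n >= 10; an exact-style permutation test
#' (B resamples) below that. Ties are handled by midranks; if either
#' variable is constant the correlation is undefined and `NA` is returned.
#'
#' @param x,y Numeric vectors.
#' @param B Permutation resamples for small n.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y, B = 2000) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant input or n < 3)"))
  rho <- stats::cor(rank(x), rank(y))
  if (n >= 10) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    return(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                method = "large-sample approximation"))
  }
  rx <- rank(x)
  perm <- replicate(B, stats::cor(rx, rank(sample(y))))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (B + 1)
  list(rho = rho, p_value = p, n = n, method = "permutation")
}

#' Glide asymmetry versus relative tissue density
#'
#' Denser-than-seawater whales are expected to glide relatively more during
#' descent, and buoyant whales more during ascent. For each deployment this
#' computes relative tissue density (posterior mean tissue density divided
#' by the deployment-mean seawater density at its glide depths) and the
#' glide asymmetry (percent time gliding in ascent minus percent in descent
#' over non-feeding dives, i.e. dives with zero detected lunges), and the
#' Spearman rank correlation between the two.
#'
#' @param fit A `glide_fit` with individual tissue-density estimates.
#' @param kin_list List of `tag_kinematics`, one per deployment.
#' @param glides Glide table data frame (for deployment-mean `rho_sw`).
#' @param min_deployments Correlation omitted (with a warning) below this.
#' @return List of class `asymmetry_analysis`: `records` (per-deployment
#'   relative density and asymmetry) and `correlation`
#'   (see [spearman_test()]), or `NULL` when omitted.
#' @export
glide_asymmetry_analysis <- function(fit, kin_list, glides,
                                     min_deployments = 5) {
  ind <- fit$summaries$individuals
  if (is.null(ind) || is.null(ind$rho_mean))
    stop("fit has no individual tissue-density estimates; ",
         "use a structure with individual rho")
  names(kin_list) <- vapply(kin_list, `[[`, "", "deployment_id")
  recs <- lapply(seq_len(nrow(ind)), function(i) {
    id <- ind$deployment_id[i]
    kin <- kin_list[[id]]
    if (is.null(kin)) return(NULL)
    pct <- phase_glide_pct(kin, feeding = FALSE)
    gsub_ <- glides[glides$deployment_id == id, , drop = FALSE]
    rel <- ind$rho_mean[i] / mean(gsub_$rho_sw)
    data.frame(deployment_id = id, relative_density = rel,
               asymmetry = unname(pct["ascent"] - pct["descent"]))
  })
  records <- do.call(rbind, recs)
  correlation <- NULL
  n_ok <- sum(is.finite(records$relative_density) &
                is.finite(records$asymmetry))
  if (n_ok < min_deployments) {
    warning("only ", n_ok, " deployments with defined asymmetry; ",
            "correlation omitted")
  } else {
    correlation <- spearman_test(records$relative_density,
                                 records$asymmetry)
  }
  structure(list(records = records, correlation = correlation),
            class = "asymmetry_analysis")
}

#' @export
print.asymmetry_analysis <- function(x, ...) {
  cat("Glide asymmetry vs relative tissue density (",
      nrow(x$records), " deployments)\n", sep = "")
  if (!is.null(x$correlation))
    cat("  Spearman rho = ", round(x$correlation$rho, 3),
        ", p = ", signif(x$correlation$p_value, 3), " (",
        x$correlation$method, ")\n", sep = "")
  invisible(x)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Orchestrates generate -> preprocess -> extract -> fit with one resolved
#' configuration, and writes the report bundle: per-individual and
#' global-parameter tables, dive statistics, the filter audit, convergence
#' diagnostics, a truth comparison, and a run log with versions, seeds and
#' the fully resolved configuration. Any stage failure aborts with the
#' stage name; artifacts written so far are preserved.
#'
#' @param config A named list (or path to a YAML file) with optional
#'   entries: `scenario` (arguments to [scenario_config()]), `seed`,
#'   `structures` (`"all"`, `"best"`, or character codes like `"IID"`),
#'   `schedule` (n_chains, n_iter, burn_in, thin), `priors` (arguments to
#'   [prior_spec()]), `timeseries` (simulate raw records and preprocess
#'   them, otherwise simulate the sub-glide table directly), `out_dir`.
#' @return Invisibly, a list with the fitted ranking, tables and paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("gliderun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- do.call(scenario_config, config$scenario %||% list())
  priors <- do.call(prior_spec, config$priors %||% list())
  schedule <- utils::modifyList(list(n_chains = 3, n_iter = 24000,
                                     burn_in = 12000, thin = 36),
                                config$schedule %||% list())
  timeseries <- config$timeseries %||% FALSE
  structures <- config$structures %||% "all"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (artifacts under ", out_dir, ")", call. = FALSE))
  }
  truth <- stage("generate", draw_population(scen, seed = seed))
  kin_list <- NULL
  if (timeseries) {
    kin_list <- list(); gt_rows <- list(); audits <- list()
    for (w in seq_len(scen$n_whales)) {
      sim <- stage("generate", simulate_tag_record(truth, scen, whale = w,
                                                   seed = seed))
      kin <- stage("preprocess", preprocess_tag(
        sim$record, orientation = "auto",
        lunge_method = if (scen$lunges_per_dive > 0) "speed-peak" else "none"))
      gt <- stage("extract", extract_glide_table(kin, scen$ctd))
      kin_list[[w]] <- kin
      gt_rows[[w]] <- gt$glides
      audits[[w]] <- gt$audit
    }
    glides <- do.call(rbind, gt_rows)
    audit <- audits
  } else {
    sim <- stage("generate", simulate_subglide_table(truth, scen, seed = seed))
    filt <- stage("extract", filter_subglides(sim$glides))
    glides <- filt$retained
    audit <- filt$audit
  }
  utils::write.csv(glides, file.path(out_dir, "glide_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(audit, file.path(out_dir, "filter_audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structs <- if (identical(structures, "all")) all_model_structures()
  else if (identical(structures, "best"))
    list(model_structure("individual", "individual", "dive"))
  else lapply(structures, parse_structure_code)
  ranking <- stage("fit", fit_all_structures(
    glides, structures = structs, seed = seed, priors = priors,
    n_chains = schedule$n_chains, n_iter = schedule$n_iter,
    burn_in = schedule$burn_in, thin = schedule$thin))

  best <- ranking$fits[[1]]
  tab3 <- structure_table(ranking)
  utils::write.csv(tab3, file.path(out_dir, "global_parameters.csv"),
                   row.names = FALSE)
  if (!is.null(best$summaries$individuals)) {
    ind <- best$summaries$individuals
    counts <- table(glides$deployment_id)
    ind$n_glides <- as.integer(counts[ind$deployment_id])
    utils::write.csv(ind, file.path(out_dir, "individual_estimates.csv"),
                     row.names = FALSE)
  }
  dive_stats <- NULL
  if (!is.null(kin_list)) {
    dive_stats <- do.call(rbind, lapply(kin_list, compute_dive_statistics))
    utils::write.csv(dive_stats, file.path(out_dir, "dive_statistics.csv"),
                     row.names = FALSE)
  }
  diag_ <- lapply(ranking$fits, function(f)
    if (!is.null(f)) list(structure = format(f$structure), psrf = f$psrf))
  jsonlite::write_json(diag_, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth_cmp <- list(
    truth = list(rho_g = truth$rho_g, cdam_g = truth$cdam_g,
                 vair_g = truth$vair_g),
    posterior = as.list(stats::setNames(best$summaries$global$mean,
                                        best$summaries$global$parameter)))
  jsonlite::write_json(truth_cmp, file.path(out_dir, "truth_comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- list(package = "glidedensity",
              version = as.character(utils::packageVersion("glidedensity")),
              r_version = R.version.string,
              seed = seed, schedule = schedule,
              structures = vapply(structs, format, ""),
              scenario = scen[!vapply(scen, is.function, TRUE)],
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(ranking = ranking, best = best, glides = glides,
                 audit = audit, dive_statistics = dive_stats,
                 truth = truth, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_structure_code <- function(code) {
  stopifnot(nchar(code) == 3)
  dec <- function(ch, dive_ok = FALSE) {
    switch(ch, G = "global", I = "individual",
           D = if (dive_ok) "dive" else stop("D only valid for gas volume"),
           stop("unknown structure code letter: ", ch))
  }
  ch <- strsplit(code, "")[[1]]
  model_structure(dec(ch[1]), dec(ch[2]), dec(ch[3], dive_ok = TRUE))
}

# Table-3-style layout: one row per structure with global estimates
structure_table <- function(ranking) {
  rows <- lapply(ranking$fits, function(f) {
    if (is.null(f)) return(NULL)
    g <- f$summaries$global
    get <- function(p, what) {
      r <- g[g$parameter == p, ]
      if (nrow(r) == 0) NA_real_ else r[[what]]
    }
    data.frame(structure = format(f$structure), dic = f$dic$dic,
               rho_g = get("rho.g", "mean"),
               rho_g_ci = get("rho.g", "upper") - get("rho.g", "lower"),
               rho_var = get("rho.var", "mean"),
               cdam_g = get("cdam.g", "mean"),
               cdam_g_ci = get("cdam.g", "upper") - get("cdam.g", "lower"),
               cdam_var = get("cdam.var", "mean"),
               vair_g = get("vair.g", "mean"),
               vair_g_ci = get("vair.g", "upper") - get("vair.g", "lower"),
               vair_var = get("vair.var", "mean"))
  })
  do.call(rbind, rows)
}
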