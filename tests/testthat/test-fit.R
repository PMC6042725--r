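# Bayesian estimation machinery: structures, priors, sampling contract,
# convergence diagnostics, DIC and summaries.

test_that("the structure grid has exactly 12 distinct members", {
  ss <- all_model_structures()
  expect_length(ss, 12)
  expect_equal(anyDuplicated(vapply(ss, format, "")), 0)
  expect_equal(format(model_structure("individual", "individual", "dive")),
               "IID")
})

test_that("posterior of a single free parameter matches grid quadrature", {
  cfg <- small_scenario(n_whales = 1, dives_per_whale = 2)
  tr <- draw_population(cfg, seed = 9, rho_sd = 0, cdam_sd = 0, vair_sd = 0)
  sim <- simulate_subglide_table(tr, cfg, seed = 10)
  g <- sim$glides
  f <- fit_glide_model(g, model_structure("global", "global", "global"),
                       fixed = list(cdam = tr$cdam_g, vair = tr$vair_g),
                       n_iter = 6000, burn_in = 2000, thin = 2,
                       n_adapt = 200, seed = 3, min_glides = 1)
  draws <- as.matrix(f$samples)[, "rho.g"]
  # brute-force quadrature over the tissue-density prior
  grid <- seq(800, 1200, length.out = 20000)
  sd_obs <- g$a_se + 0.001
  loglik <- vapply(grid, function(r) {
    mu <- glide_acceleration(r, tr$cdam_g, tr$vair_g, g$d, g$v, g$p, g$rho_sw)
    sum(dnorm(g$a, mu, sd_obs, log = TRUE))
  }, numeric(1))
  w <- exp(loglik - max(loglik)); w <- w / sum(w)
  pm <- sum(grid * w)
  psd <- sqrt(sum(grid^2 * w) - pm^2)
  expect_equal(mean(draws), pm, tolerance = 0.01 * psd / abs(pm) + 1e-5)
  expect_equal(sd(draws), psd, tolerance = 0.1)
})

test_that("a linear-in-gas model matches its closed-form posterior", {
  # with tissue density and drag fixed, the force balance is linear in gas
  # volume, so the posterior under a wide uniform prior is a (truncated)
  # normal with weighted-least-squares mean and sd
  cfg <- small_scenario(n_whales = 2, dives_per_whale = 2)
  tr <- draw_population(cfg, seed = 4, rho_sd = 0, cdam_sd = 0, vair_sd = 0)
  sim <- simulate_subglide_table(tr, cfg, seed = 5)
  g <- sim$glides
  f <- fit_glide_model(g, model_structure("global", "global", "global"),
                       fixed = list(rho = tr$rho_g, cdam = tr$cdam_g),
                       n_iter = 8000, burn_in = 2000, thin = 2,
                       n_adapt = 200, seed = 6, min_glides = 1)
  c0 <- glide_acceleration(tr$rho_g, tr$cdam_g, 0, g$d, g$v, g$p, g$rho_sw)
  b <- glide_acceleration(tr$rho_g, tr$cdam_g, 1, g$d, g$v, g$p, g$rho_sw) - c0
  s2 <- (g$a_se + 0.001)^2
  mstar <- sum(b * (g$a - c0) / s2) / sum(b^2 / s2)
  sdstar <- 1 / sqrt(sum(b^2 / s2))
  draws <- as.matrix(f$samples)[, "vair.g"]
  expect_equal(mean(draws), mstar, tolerance = 3 * sdstar / sqrt(length(draws)) * 5)
  expect_equal(sd(draws), sdstar, tolerance = 0.1)
})

test_that("sampling is seed-reproducible and respects truncation bounds", {
  cfg <- small_scenario(n_whales = 2, dives_per_whale = 2)
  tr <- draw_population(cfg, seed = 2)
  sim <- simulate_subglide_table(tr, cfg, seed = 2)
  args <- list(glides = sim$glides,
               structure = model_structure("global", "global", "global"),
               n_iter = 1500, burn_in = 500, thin = 2, n_adapt = 100,
               seed = 42, min_glides = 1)
  f1 <- do.call(fit_glide_model, args)
  f2 <- do.call(fit_glide_model, args)
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
  f3 <- do.call(fit_glide_model, utils::modifyList(args, list(seed = 43)))
  expect_false(identical(as.matrix(f1$samples), as.matrix(f3$samples)))
  d <- as.matrix(f1$samples)
  expect_true(all(d[, "rho.g"] >= 800 & d[, "rho.g"] <= 1200))
  expect_true(all(d[, "cdam.g"] >= 1 & d[, "cdam.g"] <= 20))  # 1e-6 scale
  expect_true(all(d[, "vair.g"] >= 5 & d[, "vair.g"] <= 80))
})

test_that("a flat likelihood returns the truncated drag prior", {
  # one deployment with an enormous observation error: the drag posterior
  # must reproduce the truncated-normal prior moments
  g <- data.frame(deployment_id = "x", dive_id = 1, d = 50, v = 1.5,
                  p = -0.8, a = 0, a_se = 1e5, rho_sw = 1026)
  f <- fit_glide_model(g, model_structure("global", "global", "global"),
                       fixed = list(rho = 1031, vair = 28),
                       n_iter = 22000, burn_in = 2000, thin = 2,
                       n_adapt = 200, seed = 8, min_glides = 1)
  draws <- as.matrix(f$samples)[, "cdam.g"]
  alpha <- (1 - 7) / 2; beta <- (20 - 7) / 2
  m_trunc <- 7 + 2 * (dnorm(alpha) - dnorm(beta)) /
    (pnorm(beta) - pnorm(alpha))
  expect_true(all(draws >= 1 & draws <= 20))
  expect_equal(mean(draws), m_trunc, tolerance = 0.02)
})

test_that("potential scale reduction flags unmixed chains", {
  make_chains <- function(means) coda::mcmc.list(lapply(means, function(m)
    coda::mcmc(matrix(rnorm(333, m), dimnames = list(NULL, "theta")))))
  set.seed(1)
  same <- gelman_rubin(make_chains(c(0, 0, 0)))
  expect_lt(abs(same$psrf - 1), 0.05)
  expect_false(same$flagged)
  apart <- gelman_rubin(make_chains(c(0, 100, 0)))
  expect_gt(apart$psrf, 10)
  expect_true(apart$flagged)
  expect_error(gelman_rubin(make_chains(0)), "2 chains")
  # well-mixed chains rarely flag: simulate over seeds
  ok <- 0
  for (s in 1:40) {
    set.seed(s)
    if (gelman_rubin(make_chains(c(0, 0, 0)))$psrf < 1.05) ok <- ok + 1
  }
  expect_gte(ok, 36)
})

test_that("DIC components behave like a deviance-based criterion", {
  cfg <- small_scenario(n_whales = 2, dives_per_whale = 2)
  tr <- draw_population(cfg, seed = 4, rho_sd = 0, cdam_sd = 0, vair_sd = 0)
  sim <- simulate_subglide_table(tr, cfg, seed = 5)
  # zero-parameter model: effective parameter count 0, DIC = fixed deviance
  f0 <- fit_glide_model(sim$glides, model_structure(),
                        fixed = list(rho = tr$rho_g, cdam = tr$cdam_g,
                                     vair = tr$vair_g),
                        n_iter = 500, burn_in = 100, thin = 1, n_adapt = 50,
                        seed = 2, min_glides = 1)
  expect_equal(f0$dic$pd, 0)
  expect_equal(f0$dic$dic, f0$dic$dhat)
  # one free parameter: effective count near 1
  f1 <- fit_glide_model(sim$glides, model_structure(),
                        fixed = list(cdam = tr$cdam_g, vair = tr$vair_g),
                        n_iter = 8000, burn_in = 2000, thin = 2,
                        n_adapt = 200, seed = 3, min_glides = 1)
  expect_equal(f1$dic$pd, 1, tolerance = 0.2)
  # freeing a parameter never worsens the fit at the posterior mean (small
  # slack for Monte-Carlo error in locating the posterior mean)
  expect_lte(f1$dic$dhat, f0$dic$dhat + 0.1)
  f3 <- fit_glide_model(sim$glides, model_structure(),
                        n_iter = 8000, burn_in = 2000, thin = 2,
                        n_adapt = 200, seed = 3, min_glides = 1)
  expect_lte(f3$dic$dhat, f1$dic$dhat + 2)
  # half-variance alternative is available and positive here
  expect_gt(compute_dic(f1, pd_method = "half-var")$pd, 0)
})

test_that("posterior summaries report means and central 95 percent intervals", {
  # degenerate chain: zero-width interval at the repeated draw
  m <- matrix(rep(c(1031, 9, 28), each = 100), ncol = 3,
              dimnames = list(NULL, c("rho.g", "cdam.g", "vair.g")))
  f <- fake_fit(list(m, m))
  s <- summarize_posterior(f)$global
  expect_equal(s$mean[s$parameter == "rho.g"], 1031)
  expect_equal(s$lower, s$upper)
  # standard-normal draws: interval close to +/- 1.96 around 0
  set.seed(3)
  big <- matrix(rnorm(60000), ncol = 3,
                dimnames = list(NULL, c("rho.g", "cdam.g", "vair.g")))
  fb <- fake_fit(list(big))
  sb <- summarize_posterior(fb)$global
  r <- sb[sb$parameter == "rho.g", ]
  expect_equal(r$mean, 0, tolerance = 0.05)
  expect_equal(r$lower, -1.96, tolerance = 0.08)
  expect_equal(r$upper, 1.96, tolerance = 0.08)
  # invariant to chain concatenation order
  half1 <- big[1:10000, ]; half2 <- big[10001:20000, ]
  s12 <- summarize_posterior(fake_fit(list(half1, half2)))$global
  s21 <- summarize_posterior(fake_fit(list(half2, half1)))$global
  expect_equal(s12, s21)
  # drag scale: sampler units are 1e-6 m^2 kg^-1, reports are SI
  expect_lt(abs(sb$mean[sb$parameter == "cdam.g"]), 1e-6)
})

test_that("hierarchical fits recover known global parameters", {
  cfg <- scenario_config(n_whales = 6, dives_per_whale = 6,
                         glides_per_dive = 10)
  tr <- draw_population(cfg, seed = 21, rho_g = 1031, rho_sd = 5,
                        cdam_g = 12e-6, cdam_sd = 4e-6, vair_g = 28,
                        vair_sd = 14)
  sim <- simulate_subglide_table(tr, cfg, seed = 22)
  f <- fit_glide_model(sim$glides,
                       model_structure("individual", "individual", "dive"),
                       n_iter = 3000, burn_in = 1500, thin = 3,
                       n_adapt = 200, seed = 7, min_glides = 20)
  g <- f$summaries$global
  ci <- function(p) unlist(g[g$parameter == p, c("lower", "upper")])
  expect_true(ci("rho.g")[1] <= 1031 && 1031 <= ci("rho.g")[2])
  expect_true(ci("cdam.g")[1] <= 12e-6 && 12e-6 <= ci("cdam.g")[2])
  expect_true(ci("vair.g")[1] <= 28 && 28 <= ci("vair.g")[2])
  # individual table lines up with the deployments
  ind <- f$summaries$individuals
  expect_equal(ind$deployment_id, tr$deployment_id)
  expect_true(all(ind$rho_lower <= ind$rho_mean &
                    ind$rho_mean <= ind$rho_upper))
})

test_that("widening the glide depth range sharpens the gas-volume posterior", {
  # gas and tissue buoyancy separate when glides span a wide depth range
  base <- scenario_config(n_whales = 3, dives_per_whale = 6,
                          glides_per_dive = 12)
  tr <- draw_population(base, seed = 31, rho_sd = 0, cdam_sd = 0,
                        vair_sd = 0)
  ci_width <- function(cfg, seed) {
    sim <- simulate_subglide_table(tr, cfg, seed = seed)
    f <- fit_glide_model(sim$glides, model_structure(),
                         n_iter = 3000, burn_in = 1000, thin = 2,
                         n_adapt = 200, seed = 9, min_glides = 1)
    g <- f$summaries$global
    r <- g[g$parameter == "vair.g", ]
    r$upper - r$lower
  }
  narrow <- scenario_config(n_whales = 3, dives_per_whale = 6,
                            glides_per_dive = 12,
                            mean_depth_range = c(18, 22), max_depth = 25)
  wide <- scenario_config(n_whales = 3, dives_per_whale = 6,
                          glides_per_dive = 12,
                          mean_depth_range = c(150, 250))
  expect_lt(ci_width(wide, 101), ci_width(narrow, 101))
})
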