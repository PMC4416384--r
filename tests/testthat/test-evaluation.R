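# shared fitted fixture for the evaluation tests (computed once, lazily)
eval_fx <- local({
  env <- new.env()
  function() {
    if (is.null(env$v)) {
      d <- make_rich_dataset(n = 20, seed = 303)
      f <- suppressMessages(fit_population(d, seed = 303,
                                           compute_se = FALSE))
      pd <- suppressMessages(fit_pd_sequential(d, f, compute_se = FALSE))
      env$v <- list(d = d, f = f, pd = pd)
    }
    env$v
  }
})

# a degenerate "fit" at given estimates, for simulation-only checks
fake_fit <- function(data, estimates) {
  structure(list(endpoint = "pk", estimates = estimates,
                 estimated = names(estimates),
                 model = pk_model_spec(), subjects = data$subjects,
                 doses = data$doses,
                 ebes = matrix(0, nrow(data$subjects), 3,
                               dimnames = list(data$subjects$id,
                                               c("eta_cl", "eta_v",
                                                 "eta_kf")))),
            class = "htb_fit")
}

truth_estimates <- c(theta1 = 0.2, theta2 = 8.3, theta3 = 0.341,
                     theta4 = 0.845, omega2_cl = 0.149^2,
                     omega2_v = 0.095^2, omega2_kf = 0.88^2,
                     sigma_prop2 = 0.098, sigma_add2 = 0)

test_that("vpc bands are ordered, collapse without variability, and track the typical curve", {
  d <- make_rich_dataset(n = 8, seed = 201)
  expect_equal(formals(vpc)$n_rep, 1000)  # study default
  zero_var <- truth_estimates
  zero_var[c("omega2_cl", "omega2_v", "omega2_kf", "sigma_prop2")] <- 0
  # with zero variability and a common weight the three bands collapse
  # onto the typical-value curve
  deq <- simulate_trial(simulation_config(
    n_subjects = 4, weight_mean = 71.65, weight_bounds = c(71.65, 71.65),
    seed = 201))
  v0 <- vpc(fake_fit(deq, zero_var), deq, n_rep = 20, seed = 5)
  expect_equal(v0$bands$p5, v0$bands$p95, tolerance = 1e-12)
  typ <- concentration(study_design()$regimen, v0$bands$time,
                       individual_params(theta_pk(), 71.65))
  expect_equal(v0$bands$p50, typ, tolerance = 1e-9)
  v <- vpc(fake_fit(d, truth_estimates), d, n_rep = 200, seed = 5)
  expect_true(all(v$bands$p5 <= v$bands$p50 + 1e-12))
  expect_true(all(v$bands$p50 <= v$bands$p95 + 1e-12))
  # median band at the 168 h trough ~ typical trough (oracle: closed form
  # median over weights; BSV is median-zero so compare within MC slack)
  th <- theta_pk()
  reg <- study_design()$regimen
  typ <- median(sapply(d$subjects$weight, function(w)
    concentration(reg, 168, individual_params(th, w))))
  got <- v$bands$p50[v$bands$time == 168]
  expect_equal(got, typ, tolerance = 0.1)
  # determinism by seed
  v2 <- vpc(fake_fit(d, truth_estimates), d, n_rep = 200, seed = 5)
  expect_identical(v$bands, v2$bands)
})

test_that("bootstrap of identical noise-free subjects has zero-width CIs", {
  des <- study_design()
  th <- theta_pk()
  f <- concentration(des$regimen, des$pk_times[-1],
                     individual_params(th, 71.65))
  # a touch of shared noise keeps the likelihood bounded; subjects stay
  # identical so resampling cannot change the fit
  set.seed(7)
  f <- f * (1 + rnorm(length(f), 0, 0.01))
  n <- 4
  d <- pkpd_dataset(
    data.frame(id = 1:n, weight = 71.65),
    do.call(rbind, lapply(1:n, function(i)
      data.frame(id = i, time = des$regimen$time,
                 amount = des$regimen$amount))),
    do.call(rbind, lapply(1:n, function(i)
      data.frame(id = i, time = des$pk_times[-1], conc = f))),
    data.frame(id = numeric(0), time = numeric(0), dv = numeric(0)))
  m <- pk_model_spec(fixed = c("omega2_cl", "omega2_v", "omega2_kf"),
                     init = list(omega2_cl = 1e-10, omega2_v = 1e-10,
                                 omega2_kf = 1e-10))
  b <- suppressMessages(bootstrap_model(d, m, n_rep = 3, seed = 9))
  expect_equal(b$n_failed, 0)
  width <- b$summary$upper - b$summary$lower
  expect_true(all(width / pmax(abs(b$summary$median), 1e-12) < 1e-4))
})

test_that("bootstrap medians track the point estimates on well-behaved data", {
  expect_equal(formals(bootstrap_model)$n_rep, 1000)  # study default
  fx <- eval_fx()
  b <- suppressMessages(bootstrap_model(fx$d, n_rep = 8, seed = 17))
  expect_lte(b$n_failed, 1)
  med_th1 <- b$summary$median[b$summary$parameter == "theta1"]
  expect_equal(med_th1, unname(fx$f$estimates["theta1"]), tolerance = 0.05)
})

test_that("css_min matches the superposition-to-convergence oracle and the study estimate", {
  th <- theta_pk(0.2, 8.3, 0.341)
  got <- css_min(th, dose = 600, tau = 24)
  oracle <- css_min_oracle(0.2, 8.3, 0.341, 600, 24)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_equal(got, 103.5, tolerance = 0.10)
  # kf = ke degeneracy: continuous limit
  ke <- 0.2 / 8.3
  at <- css_min(theta_pk(0.2, 8.3, ke), dose = 600, tau = 24)
  near <- css_min(theta_pk(0.2, 8.3, ke * (1 + 1e-7)), dose = 600, tau = 24)
  expect_equal(at, near, tolerance = 1e-5)
  expect_error(css_min(theta_pk(1e-13, 8.3, 0.341)), "floor")
})

test_that("accumulation factor formula and limits", {
  expect_equal(accumulation_factor(0.2 / 8.3, 24), 2.277, tolerance = 1e-3)
  expect_equal(accumulation_factor(0.2 / 8.3, 24), 2.26, tolerance = 0.02)
  expect_equal(accumulation_factor(100, 24), 1)
  expect_error(accumulation_factor(0, 24), "ke > 0")
})

test_that("ipa_table: zero predicted at pre-dose, saturation at high exposure, enumeration", {
  fx <- eval_fx()
  tab <- ipa_table(fx$pd, fx$f, fx$d)
  t0 <- tab[tab$time == 0, ]
  expect_equal(t0$predicted, 0L)
  expect_equal(t0$n, 20L)
  # 196 h (4 h after the last dose): exposure far above EC50 for everyone
  t196 <- tab[tab$time == 196, ]
  expect_gte(t196$predicted, t196$n - 2)
  # enumeration oracle for one mid time
  tmid <- 48
  ids <- fx$d$pd$id[fx$d$pd$time == tmid]
  nat <- fx$f$estimates
  th <- theta_pk(nat[["theta1"]], nat[["theta2"]], nat[["theta3"]],
                 wt_cl = nat[["theta4"]])
  psum <- 0
  for (id in ids) {
    w <- fx$d$subjects$weight[fx$d$subjects$id == id]
    p <- individual_params(th, w, fx$f$ebes[as.character(id), ])
    cc <- concentration(subject_regimen(fx$d, id), tmid, p)
    ec50_i <- fx$pd$estimates[["ec50"]] *
      exp(fx$pd$ebes[as.character(id), 1])
    psum <- psum + prob_ipa(cc, ec50_i, fx$pd$estimates[["gamma"]])
  }
  expect_equal(tab$predicted[tab$time == tmid], as.integer(round(psum)))
  expect_equal(tab$observed[tab$time == tmid],
               sum(fx$d$pd$dv[fx$d$pd$time == tmid]))
})

test_that("gof residuals vanish on exact data and flag misspecification", {
  # exact data at the typical curve, fit object at truth with zero etas
  des <- study_design()
  th <- theta_pk()
  f <- concentration(des$regimen, des$pk_times[-1],
                     individual_params(th, 71.65))
  d <- pkpd_dataset(
    data.frame(id = 1:2, weight = 71.65),
    do.call(rbind, lapply(1:2, function(i)
      data.frame(id = i, time = des$regimen$time,
                 amount = des$regimen$amount))),
    do.call(rbind, lapply(1:2, function(i)
      data.frame(id = i, time = des$pk_times[-1], conc = f))),
    data.frame(id = numeric(0), time = numeric(0), dv = numeric(0)))
  g0 <- gof(fake_fit(d, truth_estimates), d)
  expect_equal(g0$iwres, rep(0, nrow(g0)))
  expect_equal(g0$pred, g0$ipred)
  expect_equal(max(abs(g0$cwres)), 0, tolerance = 1e-9)

  # well-specified fit: IWRES approximately standard normal
  fx <- eval_fx()
  gg <- gof(fx$f, fx$d)
  expect_lt(abs(mean(gg$iwres)), 0.1)
  expect_gt(sd(gg$iwres), 0.7)
  expect_lt(sd(gg$iwres), 1.3)

  # misspecified kf (fixed far off, with its BSV pinned so the etas
  # cannot absorb the misfit): CWRES-vs-time trend by sign-run test
  m_bad <- pk_model_spec(fixed = c("theta3", "omega2_kf"),
                         init = list(theta3 = 5, omega2_kf = 1e-9))
  f_bad <- suppressMessages(fit_population(fx$d, m_bad, seed = 1,
                                           compute_se = FALSE))
  gb <- gof(f_bad, fx$d)
  # sign-run test on per-nominal-time mean CWRES: under a correct model
  # the 13 means are sign-random; misfit clusters them along time
  runs_z <- function(tab) {
    s <- sign(aggregate(cwres ~ time, tab, mean)$cwres)
    s <- s[s != 0]
    r <- 1 + sum(diff(s) != 0)
    n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
    mu <- 2 * n1 * n2 / n + 1
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    (r - mu) / sqrt(v)
  }
  # misfit clusters residual signs along the absorption samples
  expect_lt(runs_z(gb), -2)
  expect_gt(runs_z(gg), -2)
})
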