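# one-subject dataset with a single active random effect, for quadrature
# cross-checks of the Laplace approximation
one_eta_subject <- function(seed = 7, omega2_cl = 0.149^2, sp2 = 0.098) {
  des <- study_design()
  th <- theta_pk()
  set.seed(seed)
  eta <- rnorm(1) * sqrt(omega2_cl)
  p <- individual_params(th, 71.65, c(eta, 0, 0))
  f <- concentration(des$regimen, des$pk_times[-1], p)
  y <- f * (1 + rnorm(length(f)) * sqrt(sp2))
  data <- pkpd_dataset(
    data.frame(id = 1, weight = 71.65),
    data.frame(id = 1, time = des$regimen$time, amount = des$regimen$amount),
    data.frame(id = 1, time = des$pk_times[-1], conc = y),
    data.frame(id = numeric(0), time = numeric(0), dv = numeric(0)))
  list(data = data, y = y, times = des$pk_times[-1], regimen = des$regimen,
       th = th)
}

test_that("Laplace subject OFV matches 64-node adaptive quadrature within 0.5%", {
  for (seed in c(7, 8, 9)) {
    su <- one_eta_subject(seed)
    params <- list(theta = su$th, omega2 = c(0.149^2, 0, 0),
                   sigma = sigma_model("proportional", prop2 = 0.098))
    got <- subject_ofv(su$data, pk_model_spec(n_nodes = 1), params)
    got_agq <- subject_ofv(su$data, pk_model_spec(), params)
    g <- function(eta) {
      p <- individual_params(su$th, 71.65, c(eta, 0, 0))
      f <- concentration(su$regimen, su$times, p)
      -sum(pk_loglik_contrib(su$y, f,
                             sigma_model("proportional", prop2 = 0.098))) -
        dnorm(eta, 0, 0.149, log = TRUE)
    }
    oracle <- agq_neg2ll_oracle(g, 0.149^2, n_nodes = 64)
    expect_equal(got$ofv, oracle, tolerance = 0.005)
    # the default 5-node adaptive rule is closer still
    expect_equal(got_agq$ofv, oracle, tolerance = 0.005)
  }
})

test_that("Omega -> 0 degenerates to -2 log-likelihood at eta = 0", {
  su <- one_eta_subject(11)
  params <- list(theta = su$th, omega2 = c(0, 0, 0),
                 sigma = sigma_model("proportional", prop2 = 0.098))
  got <- subject_ofv(su$data, pk_model_spec(), params)
  f <- concentration(su$regimen, su$times,
                     individual_params(su$th, 71.65, c(0, 0, 0)))
  expect_equal(got$ofv,
               -2 * sum(pk_loglik_contrib(su$y, f,
                                          sigma_model("proportional",
                                                      prop2 = 0.098))))
  expect_equal(got$eta_hat, c(0, 0, 0))
})

test_that("noise-free data at the typical curve gives eta_hat ~ 0", {
  des <- study_design()
  th <- theta_pk()
  f <- concentration(des$regimen, des$pk_times[-1],
                     individual_params(th, 71.65, c(0, 0, 0)))
  data <- pkpd_dataset(
    data.frame(id = 1, weight = 71.65),
    data.frame(id = 1, time = des$regimen$time, amount = des$regimen$amount),
    data.frame(id = 1, time = des$pk_times[-1], conc = f),
    data.frame(id = numeric(0), time = numeric(0), dv = numeric(0)))
  # additive error keeps the joint density symmetric about eta = 0 (the
  # proportional model's log-variance term shifts the mode slightly)
  params <- list(theta = th, omega2 = c(0.149^2, 0.095^2, 0.88^2),
                 sigma = sigma_model("additive", add2 = 4))
  got <- subject_ofv(data, pk_model_spec(error = "additive"), params)
  expect_lt(max(abs(got$eta_hat)), 1e-3)
})

test_that("OFV shifts by exactly 2 n log(c) when data and dose are scaled", {
  su <- one_eta_subject(13)
  params <- list(theta = su$th, omega2 = c(0.149^2, 0, 0),
                 sigma = sigma_model("proportional", prop2 = 0.098))
  base <- subject_ofv(su$data, pk_model_spec(), params)
  cfac <- 2
  scaled <- su$data
  scaled$pk$conc <- scaled$pk$conc * cfac
  scaled$doses$amount <- scaled$doses$amount * cfac
  got <- subject_ofv(scaled, pk_model_spec(), params)
  n <- nrow(su$data$pk)
  expect_equal(got$ofv, base$ofv + 2 * n * log(cfac), tolerance = 1e-6)
  expect_equal(got$eta_hat, base$eta_hat, tolerance = 1e-4)
})

test_that("fit_population recovers theta to <1% on near-noise-free data", {
  pars <- default_parameters()
  pars$omega2 <- c(cl = 1e-12, v = 1e-12, kf = 1e-12)
  pars$sigma <- sigma_model("proportional", prop2 = 1e-6)
  d <- simulate_trial(simulation_config(n_subjects = 6, seed = 21,
                                        parameters = pars))
  m <- pk_model_spec(fixed = c("omega2_cl", "omega2_v", "omega2_kf"),
                     init = list(omega2_cl = 1e-12, omega2_v = 1e-12,
                                 omega2_kf = 1e-12))
  f <- suppressMessages(fit_population(d, m, compute_se = FALSE))
  expect_true(f$convergence$ok)
  expect_equal(unname(f$estimates["theta1"]), 0.2, tolerance = 0.01)
  expect_equal(unname(f$estimates["theta2"]), 8.3, tolerance = 0.01)
  expect_equal(unname(f$estimates["theta3"]), 0.341, tolerance = 0.01)
  expect_equal(unname(f$estimates["theta4"]), 0.845, tolerance = 0.01)
})

test_that("OFV is invariant to subject order", {
  d <- make_rich_dataset(n = 6, seed = 31)
  perm <- c(4, 2, 6, 1, 5, 3)
  d2 <- d
  d2$subjects <- d$subjects[perm, ]
  f1 <- suppressMessages(fit_population(d, compute_se = FALSE))
  f2 <- suppressMessages(fit_population(d2, compute_se = FALSE))
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-6)
})

test_that("sequential PD fit with omega fixed 0 equals the pooled logistic MLE", {
  d <- make_rich_dataset(n = 12, seed = 41)
  pk_fit <- suppressMessages(fit_population(d, compute_se = FALSE))
  pd_fit <- suppressMessages(fit_pd_sequential(
    d, pk_fit, pd_model_spec(estimate_omega = FALSE,
                             init = list(omega2_ec50 = 0)),
    compute_se = FALSE))
  # independent oracle: glm on the same individual predicted concentrations
  nat <- pk_fit$estimates
  th <- theta_pk(nat[["theta1"]], nat[["theta2"]], nat[["theta3"]],
                 wt_cl = nat[["theta4"]], wt_v = 1)
  cc <- dv <- numeric(0)
  for (i in seq_len(nrow(d$subjects))) {
    id <- d$subjects$id[i]
    pd <- d$pd[d$pd$id == id, ]
    p <- individual_params(th, d$subjects$weight[i],
                           pk_fit$ebes[as.character(id), ])
    cc <- c(cc, concentration(subject_regimen(d, id), pd$time, p))
    dv <- c(dv, pd$dv)
  }
  keep <- cc > 0
  g <- suppressWarnings(glm(dv[keep] ~ log(cc[keep]), family = binomial()))
  gamma_glm <- unname(coef(g)[2])
  ec50_glm <- exp(-unname(coef(g)[1]) / gamma_glm)
  expect_equal(unname(pd_fit$estimates[["gamma"]]), gamma_glm,
               tolerance = 1e-3)
  expect_equal(unname(pd_fit$estimates[["ec50"]]), ec50_glm,
               tolerance = 1e-3)
})

test_that("fit_pd_sequential errors when a subject lacks PK EBEs", {
  d <- make_rich_dataset(n = 6, seed = 51)
  d5 <- d
  d5$subjects <- d$subjects[1:5, ]
  d5$doses <- d$doses[d$doses$id <= 5, ]
  d5$pk <- d$pk[d$pk$id <= 5, ]
  d5$pd <- d$pd[d$pd$id <= 5, ]
  pk_fit <- suppressMessages(fit_population(d5, compute_se = FALSE))
  expect_error(fit_pd_sequential(d, pk_fit), "6")
})

test_that("lrt applies the 3.84 decision rule with inclusive boundary", {
  r <- lrt(100 + 30.782, 100, df = 1)
  expect_true(r$significant)
  expect_lt(r$p_value, 0.001)
  expect_true(lrt(103.84, 100, df = 1)$significant)
  expect_false(lrt(103.83, 100, df = 1)$significant)
  r0 <- lrt(100, 100, df = 1)
  expect_false(r0$significant)
  expect_equal(r0$p_value, 1)
  expect_error(lrt(1, 0, df = 0), "df")
  # negative decrease allowed, never significant
  expect_false(lrt(99, 100, df = 1)$significant)
})

test_that("covariate screen retains weight for an allometric eta and ranks it first", {
  set.seed(61)
  n <- 50
  w <- sample_weights(n, seed = 61)
  ebes <- data.frame(eta_cl = 0.845 * log(w / 71.65) + rnorm(n, 0, 0.05),
                     eta_v = rnorm(n, 0, 0.1))
  covs <- data.frame(weight = w, age = runif(n, 21, 28))
  sc <- covariate_screen(ebes, covs)
  expect_equal(sc$eta[1], "eta_cl")
  expect_equal(sc$covariate[1], "weight")
  expect_true(sc$retained[1])
  expect_false(any(sc$retained[sc$covariate == "age"]))
})

test_that("covariate screen type-I retention under the null is near nominal", {
  set.seed(71)
  hits <- 0L
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    ebes <- data.frame(eta_cl = rnorm(20, 0, 0.15))
    covs <- data.frame(weight = rnorm(20, 70.8, 9))
    hits <- hits + any(covariate_screen(ebes, covs)$retained)
  }
  # AIC drop >= 3.84 <=> deviance drop >= 5.84 <=> p ~ 0.016 per basis;
  # union over two correlated bases stays below ~0.03, allow MC slack
  expect_lt(hits / n_rep, 0.08)
})

test_that("covariate screen skips constant covariates and checks n", {
  ebes <- data.frame(eta_cl = rnorm(10))
  expect_message(covariate_screen(ebes, data.frame(height = rep(176, 10),
                                                   weight = rnorm(10, 70))),
                 "constant")
  expect_error(covariate_screen(ebes[1:4, , drop = FALSE],
                                data.frame(weight = rnorm(4))), ">= 6")
})

test_that("standard_errors is exact on a quadratic objective", {
  fn <- function(p) 0.5 * (4 * (p[1] - 1)^2 + 9 * (p[2] + 2)^2)
  se <- standard_errors(fn, c(1, -2))
  expect_true(se$ok)
  expect_equal(se$se, c(1 / 2, 1 / 3), tolerance = 1e-6)
  # non-identified direction -> flagged
  fn2 <- function(p) 0.5 * (p[1] - p[2])^2
  expect_false(standard_errors(fn2, c(0, 0))$ok)
})

test_that("RSE shrinks roughly as 1/sqrt(n)", {
  # variance components fixed at truth so no estimate sits on a bound and
  # the (theta, sigma) Hessian stays positive definite at both sizes
  truth_om <- list(omega2_cl = 0.149^2, omega2_v = 0.095^2,
                   omega2_kf = 0.88^2)
  m <- pk_model_spec(fixed = c("omega2_cl", "omega2_v", "omega2_kf"),
                     init = truth_om)
  f1 <- suppressMessages(fit_population(
    simulate_trial(simulation_config(n_subjects = 10, seed = 81)),
    m, seed = 81))
  f2 <- suppressMessages(fit_population(
    simulate_trial(simulation_config(n_subjects = 40, seed = 81)),
    m, seed = 81))
  expect_true(f1$convergence$ok && f2$convergence$ok)
  ratio <- f1$rse_percent["theta1"] / f2$rse_percent["theta1"]
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("shrinkage formula and Monte-Carlo behaviour", {
  expect_equal(shrinkage(rep(0, 10), 0.25), 100)
  x <- c(-1, 1) * sqrt(0.3) / sqrt(var(c(-1, 1)))
  expect_equal(shrinkage(x, 0.3), 0, tolerance = 1e-9)
  set.seed(91)
  eta <- rnorm(4000, 0, sqrt(0.25 * 0.3))
  expect_equal(shrinkage(eta, 0.3), 50, tolerance = 0.05)
  expect_error(shrinkage(0.1, 0.3), ">= 2")
  expect_error(shrinkage(c(0, 1), 0), "> 0")
})
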