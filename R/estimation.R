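#' Model specifications for population fitting
#'
#' `pk_model_spec()` describes the PK endpoint: covariate structure
#' (allometric power of weight on CL/F with estimated exponent and fixed
#' exponent 1 on V/F, or no covariate), residual-error structure, initial
#' values and fixed parameters.  `pd_model_spec()` describes the binary
#' PD endpoint (EC50, gamma, lognormal BSV on EC50).
#'
#' @param n_nodes per-dimension adaptive Gauss-Hermite nodes for the
#'   random-effect integral (tensor product over active dimensions,
#'   centred at the conditional mode); 1 gives the pure Laplace / FOCE-I
#'   analog, which is noticeably biased here (see the methods vignette)
#' @param covariate `"power"` (weight on CL/F and V/F) or `"none"`
#' @param estimate_exponent estimate the CL/F weight exponent?  (the V/F
#'   exponent is fixed at 1 under `"power"`)
#' @param error residual error structure for concentrations
#' @param init named list of initial values overriding the defaults
#'   (`theta1`, `theta2`, `theta3`, `theta4`, `omega2_cl`, `omega2_v`,
#'   `omega2_kf`, `sigma_prop2`, `sigma_add2`)
#' @param fixed character vector of parameter names to hold at their
#'   initial value
#' @param ref_weight reference weight (kg) for the covariate model
#' @return a list of class `"pk_model_spec"` / `"pd_model_spec"`
#' @export
pk_model_spec <- function(covariate = c("power", "none"),
                          estimate_exponent = TRUE,
                          error = c("proportional", "additive", "combined"),
                          init = list(), fixed = character(),
                          ref_weight = 71.65, n_nodes = 3) {
  stopifnot(n_nodes >= 1)
  structure(list(endpoint = "pk", covariate = match.arg(covariate),
                 estimate_exponent = estimate_exponent,
                 error = match.arg(error), init = init, fixed = fixed,
                 ref_weight = ref_weight, n_nodes = n_nodes),
            class = "pk_model_spec")
}

#' @rdname pk_model_spec
#' @param estimate_omega estimate the EC50 BSV variance?  gamma carries no
#'   BSV (its variance is fixed at 0)
#' @param gamma_bounds box for the Hill shape factor
#' @param n_nodes adaptive Gauss-Hermite nodes for the 1-D EC50 integral;
#'   1 reduces to the Laplace approximation (which is visibly biased for
#'   Bernoulli data, see the methods vignette)
#' @export
pd_model_spec <- function(init = list(), fixed = character(),
                          estimate_omega = TRUE,
                          gamma_bounds = c(0.1, 100), n_nodes = 15) {
  stopifnot(n_nodes >= 1)
  structure(list(endpoint = "pd", init = init, fixed = fixed,
                 estimate_omega = estimate_omega,
                 gamma_bounds = gamma_bounds, n_nodes = n_nodes),
            class = "pd_model_spec")
}

# ---- internal: flattened per-subject arrays for the C++ backend --------

build_pk_arrays <- function(data, quiet = FALSE) {
  ids <- data$subjects$id
  obs_t <- obs_y <- dose_t <- dose_a <- numeric(0)
  obs_ptr <- dose_ptr <- integer(length(ids) + 1L)
  n_blq <- 0L
  for (i in seq_along(ids)) {
    pk <- data$pk[data$pk$id == ids[i], , drop = FALSE]
    pk <- pk[order(pk$time), , drop = FALSE]
    n_blq <- n_blq + sum(pk$blq)
    pk <- pk[!pk$blq, , drop = FALSE]
    d <- data$doses[data$doses$id == ids[i], , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    obs_t <- c(obs_t, pk$time); obs_y <- c(obs_y, pk$conc)
    dose_t <- c(dose_t, d$time); dose_a <- c(dose_a, d$amount)
    obs_ptr[i + 1L] <- length(obs_t)
    dose_ptr[i + 1L] <- length(dose_t)
  }
  if (n_blq > 0 && !quiet)
    message(n_blq, " BLQ concentration record(s) (< ", LLOQ,
            " ug/mL) excluded from the likelihood")
  list(ids = ids, weights = data$subjects$weight,
       obs_t = obs_t, obs_y = obs_y, obs_ptr = obs_ptr,
       dose_t = dose_t, dose_a = dose_a, dose_ptr = dose_ptr)
}

pk_default_init <- function(model) {
  init <- list(theta1 = 0.3, theta2 = 12, theta3 = 0.6, theta4 = 0.75,
               omega2_cl = 0.05, omega2_v = 0.05, omega2_kf = 0.3,
               sigma_prop2 = 0.05, sigma_add2 = 1)
  init[names(model$init)] <- model$init
  init
}

pk_par_names <- function(model) {
  nm <- c("theta1", "theta2", "theta3",
          if (model$covariate == "power" && model$estimate_exponent) "theta4",
          "omega2_cl", "omega2_v", "omega2_kf",
          if (model$error %in% c("proportional", "combined")) "sigma_prop2",
          if (model$error %in% c("additive", "combined")) "sigma_add2")
  setdiff(nm, model$fixed)
}

# natural named vector (estimated + fixed) from a transformed estimate
# vector; theta4 is the only untransformed parameter
pk_natural <- function(par_trans, est_names, init, model) {
  full <- unlist(init)
  for (j in seq_along(est_names)) {
    nm <- est_names[j]
    full[nm] <- if (nm == "theta4") par_trans[j] else exp(par_trans[j])
  }
  if (model$covariate == "none") full["theta4"] <- 0
  if (model$error == "proportional") full["sigma_add2"] <- 0
  if (model$error == "additive") full["sigma_prop2"] <- 0
  full
}

pk_ofv_engine <- function(nat, arr, model, eta_env) {
  wr <- arr$weights / model$ref_weight
  e_cl <- if (model$covariate == "power") nat[["theta4"]] else 0
  e_v <- if (model$covariate == "power") 1 else 0
  res <- laplace_pk_ofv_cpp(
    arr$obs_t, arr$obs_y, arr$obs_ptr, arr$dose_t, arr$dose_a, arr$dose_ptr,
    nat[["theta1"]] * wr^e_cl, nat[["theta2"]] * wr^e_v,
    rep(nat[["theta3"]], length(arr$ids)),
    c(nat[["omega2_cl"]], nat[["omega2_v"]], nat[["omega2_kf"]]),
    nat[["sigma_prop2"]], nat[["sigma_add2"]], eta_env$eta,
    if (is.null(model$n_nodes)) 1L else model$n_nodes)
  eta_env$eta <- res$eta
  eta_env$ok <- res$ok
  res$ofv
}

#' Laplace objective-function contribution of one subject
#'
#' Inner optimisation finds the conditional mode eta-hat of the joint log
#' density (data given eta, plus the N(0, Omega) prior); the -2 log
#' marginal likelihood contribution is the Laplace approximation using the
#' Hessian at eta-hat.  Residual variance is evaluated at the conditional
#' prediction (interaction).  With all omega^2 = 0 the contribution
#' degenerates to -2 * sum(log-density at eta = 0).
#'
#' @param data a [pkpd_dataset()]
#' @param model a [pk_model_spec()]
#' @param params named list with `theta` ([theta_pk()]), `omega2`
#'   (3-vector), `sigma` ([sigma_model()]), e.g. [default_parameters()]
#' @param id subject id (defaults to the only subject)
#' @return list with `ofv` (the -2 log-likelihood contribution) and
#'   `eta_hat`
#' @export
subject_ofv <- function(data, model = pk_model_spec(), params, id = NULL) {
  if (is.null(id)) {
    if (nrow(data$subjects) != 1) stop("give a subject id")
    id <- data$subjects$id[1]
  }
  sub <- pkpd_dataset(data$subjects[data$subjects$id == id, , drop = FALSE],
                      data$doses[data$doses$id == id, , drop = FALSE],
                      data$pk[data$pk$id == id, , drop = FALSE],
                      data$pd[data$pd$id == id, , drop = FALSE])
  arr <- build_pk_arrays(sub, quiet = TRUE)
  th <- params$theta
  nat <- c(theta1 = th$cl, theta2 = th$v, theta3 = th$kf, theta4 = th$wt_cl,
           omega2_cl = unname(params$omega2[1]),
           omega2_v = unname(params$omega2[2]),
           omega2_kf = unname(params$omega2[3]),
           sigma_prop2 = params$sigma$prop2, sigma_add2 = params$sigma$add2)
  env <- new.env(); env$eta <- matrix(0, 1, 3)
  model$ref_weight <- th$ref_weight
  ofv <- pk_ofv_engine(nat, arr, model, env)
  list(ofv = ofv, eta_hat = drop(env$eta))
}

#' Fit the population PK model by Laplace (FOCE-style) estimation
#'
#' Outer optimisation of the summed per-subject Laplace -2 log marginal
#' likelihood over the fixed effects, BSV variances and residual variance.
#' Positive parameters are optimised in log space; the inner conditional
#' modes are warm-started across outer iterations.  Deterministic given
#' data, initial values and seed (the seed only drives restart
#' perturbations after a failed convergence).
#'
#' @param data a [pkpd_dataset()] with at least 2 subjects
#' @param model a [pk_model_spec()]
#' @param init named list of initial values (overrides the model spec's)
#' @param seed integer, used only for multi-start perturbations
#' @param compute_se compute standard errors from the central-difference
#'   Hessian of OFV/2 (skip to save time in resampling loops)
#' @param verbose log the OFV trajectory (one `message()` line per outer
#'   objective evaluation)
#' @return object of class `"htb_fit"`: named `estimates`, `se`,
#'   `rse_percent`, `ofv`, `ebes` (subjects x eta matrix), \code{shrinkage_percent},
#'   `convergence` diagnostics, plus the model and subject table.
#' @examples
#' \donttest{
#' d <- simulate_trial(simulation_config(n_subjects = 12, seed = 7))
#' f <- fit_population(d, compute_se = FALSE)
#' f$estimates
#' }
#' @export
fit_population <- function(data, model = pk_model_spec(), init = NULL,
                           seed = 1, compute_se = TRUE, verbose = FALSE) {
  stopifnot(inherits(data, "pkpd_dataset"))
  if (nrow(data$subjects) < 2) stop("need >= 2 subjects")
  if (model$covariate == "power" && anyNA(data$subjects$weight))
    stop("weight covariate model requires WT for all subjects")
  full_init <- pk_default_init(model)
  if (!is.null(init)) full_init[names(init)] <- init
  est <- pk_par_names(model)
  arr <- build_pk_arrays(data)
  n <- length(arr$ids)
  env <- new.env(); env$eta <- matrix(0, n, 3)
  n_eval <- 0L
  obj <- function(par_trans) {
    nat <- pk_natural(par_trans, est, full_init, model)
    v <- try(pk_ofv_engine(nat, arr, model, env), silent = TRUE)
    v <- if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
    n_eval <<- n_eval + 1L
    if (isTRUE(verbose))
      message(sprintf("eval %4d: OFV %.6f", n_eval, v))
    v
  }
  start <- vapply(est, function(nm)
    if (nm == "theta4") full_init[[nm]] else log(full_init[[nm]]), 0)
  lower <- ifelse(est == "theta4", -5, log(1e-8))
  upper <- ifelse(est == "theta4", 5,
                  ifelse(grepl("^theta", est), log(1e6), log(25)))
  control <- list(iter.max = 400, eval.max = 1500, rel.tol = 1e-8)
  fit <- nlminb(start, obj, lower = lower, upper = upper, control = control)
  ok <- fit$convergence == 0 ||
    kkt_ok(obj, fit$par, lower, upper)
  restarts <- 0L
  while (!ok && restarts < 3L) {
    restarts <- restarts + 1L
    # first retry polishes from the endpoint; later ones perturb (seeded)
    pert <- if (restarts == 1L) 0 else
      with_seed(child_seed(seed, restarts),
                rnorm(length(start), 0, 0.2))
    env$eta <- matrix(0, n, 3)
    fit2 <- nlminb(fit$par + pert, obj, lower = lower, upper = upper,
                   control = control)
    if (fit2$objective <= fit$objective) fit <- fit2
    ok <- fit$convergence == 0 || kkt_ok(obj, fit$par, lower, upper)
  }
  nat <- pk_natural(fit$par, est, full_init, model)
  ofv <- pk_ofv_engine(nat, arr, model, env)  # refresh EBEs at the optimum
  ebes <- env$eta
  rownames(ebes) <- arr$ids
  colnames(ebes) <- c("eta_cl", "eta_v", "eta_kf")
  om2 <- c(nat["omega2_cl"], nat["omega2_v"], nat["omega2_kf"])
  shr <- setNames(rep(NA_real_, 3), colnames(ebes))
  for (j in 1:3) if (om2[j] > 1e-12 && n >= 2)
    shr[j] <- shrinkage(ebes[, j], om2[j])
  se <- rse <- setNames(rep(NA_real_, length(est)), est)
  se_flag <- NULL
  if (compute_se) {
    fn_nat <- function(p_nat) {
      nat2 <- nat
      nat2[est] <- p_nat
      pk_ofv_engine(nat2, arr, model, env) / 2
    }
    ses <- standard_errors(fn_nat, unname(nat[est]))
    if (ses$ok) {
      se[] <- ses$se
      rse[] <- 100 * ses$se / abs(nat[est])
    } else se_flag <- "hessian not positive definite; SEs omitted"
  }
  structure(list(
    endpoint = "pk", estimates = nat[c("theta1", "theta2", "theta3",
                                       "theta4", "omega2_cl", "omega2_v",
                                       "omega2_kf", "sigma_prop2",
                                       "sigma_add2")],
    estimated = est, se = se, rse_percent = rse, ofv = ofv, ebes = ebes,
    shrinkage_percent = shr,
    convergence = list(ok = ok, code = fit$convergence,
                       message = fit$message, restarts = restarts,
                       inner_ok_fraction = mean(env$ok),
                       se_flag = se_flag),
    model = model, subjects = data$subjects, doses = data$doses,
    n_obs = length(arr$obs_y)), class = "htb_fit")
}

# individual PK parameters of every subject in a PK fit, from the fitted
# typical values, covariates and empirical Bayes etas
individual_pk_table <- function(pk_fit) {
  nat <- pk_fit$estimates
  th <- theta_pk(nat[["theta1"]], nat[["theta2"]], nat[["theta3"]],
                 wt_cl = if (pk_fit$model$covariate == "power")
                   nat[["theta4"]] else 0,
                 wt_v = if (pk_fit$model$covariate == "power") 1 else 0,
                 ref_weight = pk_fit$model$ref_weight)
  ids <- pk_fit$subjects$id
  out <- data.frame(id = ids, cl = NA_real_, v = NA_real_, kf = NA_real_)
  for (i in seq_along(ids)) {
    p <- individual_params(th, pk_fit$subjects$weight[i],
                           pk_fit$ebes[as.character(ids[i]) == rownames(pk_fit$ebes), ])
    out$cl[i] <- p$cl; out$v[i] <- p$v; out$kf[i] <- p$kf
  }
  out
}

#' Sequential PD fit on individual predicted concentrations
#'
#' The binary probability model is estimated conditional on the PK fit:
#' each subject's concentration at the PD sampling times is predicted from
#' the individual (empirical Bayes) PK parameters, then EC50, gamma and
#' the EC50 BSV variance are estimated by the same Laplace machinery with
#' a Bernoulli likelihood.  Initial EC50/gamma come from
#' [logistic_init()] on the pooled data unless given.
#'
#' @param data a [pkpd_dataset()] with PD observations
#' @param pk_fit a PK [fit_population()] result holding EBEs for every
#'   subject with PD data
#' @param model a [pd_model_spec()]
#' @param init named list (`ec50`, `gamma`, `omega2_ec50`)
#' @param compute_se compute standard errors?
#' @return an `"htb_fit"` with estimates `ec50`, `gamma`, `omega2_ec50`
#' @export
fit_pd_sequential <- function(data, pk_fit, model = pd_model_spec(),
                              init = NULL, compute_se = TRUE) {
  stopifnot(inherits(data, "pkpd_dataset"), inherits(pk_fit, "htb_fit"),
            pk_fit$endpoint == "pk")
  pd_ids <- unique(data$pd$id)
  missing_id <- setdiff(as.character(pd_ids), rownames(pk_fit$ebes))
  if (length(missing_id))
    stop("no PK empirical Bayes estimates for subject(s): ",
         paste(missing_id, collapse = ", "))
  ipk <- individual_pk_table(pk_fit)
  conc <- dv <- numeric(0)
  ptr <- integer(length(pd_ids) + 1L)
  for (i in seq_along(pd_ids)) {
    pd <- data$pd[data$pd$id == pd_ids[i], , drop = FALSE]
    pd <- pd[order(pd$time), , drop = FALSE]
    p <- ipk[ipk$id == pd_ids[i], ]
    reg <- subject_regimen(data, pd_ids[i])
    conc <- c(conc, concentration(reg, pd$time, p))
    dv <- c(dv, pd$dv)
    ptr[i + 1L] <- length(conc)
  }
  li <- logistic_init(conc = conc, dv = dv)
  full_init <- list(
    ec50 = if (!is.na(li$ec50) && li$ec50 > 0 && !li$separation) li$ec50 else 80,
    gamma = min(max(if (!li$degenerate) abs(li$gamma) else 5,
                    model$gamma_bounds[1]), model$gamma_bounds[2]),
    omega2_ec50 = 0.04)
  full_init[names(model$init)] <- model$init
  if (!is.null(init)) full_init[names(init)] <- init
  est <- setdiff(c("ec50", "gamma", if (model$estimate_omega) "omega2_ec50"),
                 model$fixed)
  natural <- function(par_trans) {
    full <- unlist(full_init)
    full[est] <- exp(par_trans)
    full
  }
  env <- new.env(); env$eta <- rep(0, length(pd_ids))
  engine <- function(full) {
    res <- laplace_pd_ofv_cpp(conc, as.integer(dv), ptr, full[["ec50"]],
                              full[["gamma"]], full[["omega2_ec50"]],
                              env$eta, model$n_nodes)
    env$eta <- drop(res$eta)
    env$ok <- res$ok
    res$ofv
  }
  obj <- function(par_trans) {
    v <- try(engine(natural(par_trans)), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  start <- log(unlist(full_init[est]))
  lower <- setNames(log(c(ec50 = 1e-3, gamma = model$gamma_bounds[1],
                          omega2_ec50 = 1e-8)[est]), NULL)
  upper <- setNames(log(c(ec50 = 1e5, gamma = model$gamma_bounds[2],
                          omega2_ec50 = 25)[est]), NULL)
  fit <- nlminb(start, obj, lower = lower, upper = upper,
                control = list(iter.max = 300, eval.max = 1000,
                               rel.tol = 1e-8))
  ok <- fit$convergence == 0 || kkt_ok(obj, fit$par, lower, upper)
  nat <- natural(fit$par)
  ofv <- engine(nat)
  ebes <- matrix(env$eta, ncol = 1,
                 dimnames = list(pd_ids, "eta_ec50"))
  shr <- c(eta_ec50 = if (nat[["omega2_ec50"]] > 1e-12)
    shrinkage(ebes[, 1], nat[["omega2_ec50"]]) else NA_real_)
  at_bound <- abs(nat[["gamma"]] - model$gamma_bounds) < 1e-6
  se <- rse <- setNames(rep(NA_real_, length(est)), est)
  se_flag <- if (any(at_bound)) "gamma at bound; weakly identified" else NULL
  if (compute_se) {
    fn_nat <- function(p_nat) {
      full <- nat; full[est] <- p_nat
      engine(full) / 2
    }
    ses <- standard_errors(fn_nat, unname(nat[est]))
    if (ses$ok) {
      se[] <- ses$se
      rse[] <- 100 * ses$se / abs(nat[est])
    } else se_flag <- c(se_flag, "hessian not positive definite; SEs omitted")
  }
  structure(list(
    endpoint = "pd", estimates = nat, estimated = est, se = se,
    rse_percent = rse, ofv = ofv, ebes = ebes, shrinkage_percent = shr,
    convergence = list(ok = ok, code = fit$convergence,
                       message = fit$message,
                       gamma_at_bound = any(at_bound),
                       inner_ok_fraction = mean(env$ok), se_flag = se_flag),
    model = model, subjects = pk_fit$subjects, init_logistic = li,
    n_obs = length(dv)), class = "htb_fit")
}

#' @export
print.htb_fit <- function(x, ...) {
  cat("<htb_fit>", toupper(x$endpoint), "endpoint, OFV =",
      format(x$ofv, digits = 8), "\n")
  est <- data.frame(Estimate = x$estimates[x$estimated],
                    `RSE%` = round(x$rse_percent, 1), check.names = FALSE)
  print(est)
  if (length(x$shrinkage_percent))
    cat("shrinkage (%):",
        paste(names(x$shrinkage_percent),
              round(x$shrinkage_percent, 1), sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' Likelihood-ratio test on the -2 log-likelihood (OFV) scale
#'
#' Significance at the 0.05 level requires an OFV decrease of at least
#' 3.84 for one degree of freedom (the chi-squared quantile generalizes
#' for more); the boundary is inclusive.
#'
#' @param ofv_reduced,ofv_full OFV of the nested (reduced) and full model
#' @param df number of extra parameters in the full model (> 0)
#' @return list with `delta_ofv`, `p_value`, `significant`
#' @examples
#' lrt(110, 79.218, df = 1)  # delta 30.782, p < 0.001
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1) {
  if (df <= 0) stop("df must be > 0")
  delta <- ofv_reduced - ofv_full
  crit <- stats::qchisq(0.95, df)
  p <- pchisq(max(delta, 0), df, lower.tail = FALSE)
  list(delta_ofv = delta, p_value = p,
       significant = delta >= crit | (df == 1 & delta >= 3.84))
}

#' Screen covariates against empirical Bayes estimates
#'
#' For every (eta, covariate) pair, fits linear and log-linear bases on
#' the EBEs and ranks the best basis by AIC decrease against the
#' intercept-only model; candidates with a decrease of at least 3.84 are
#' retained (the additive-model screen standing in for a nonparametric
#' GAM; final inclusion is confirmed by [lrt()] on the full model).
#'
#' @param ebes matrix or data frame of per-subject etas (columns named)
#' @param covariates data frame of per-subject covariate values (numeric
#'   columns; an `id` column is ignored)
#' @param cutoff AIC decrease required for retention
#' @return data frame with columns `eta`, `covariate`, `basis`,
#'   `aic_drop`, `retained`, sorted by decreasing AIC drop
#' @export
covariate_screen <- function(ebes, covariates, cutoff = 3.84) {
  ebes <- as.data.frame(ebes)
  if (nrow(ebes) < 6) stop("need >= 6 subjects with complete covariates")
  covariates <- covariates[, setdiff(names(covariates), "id"), drop = FALSE]
  out <- list()
  for (e in names(ebes)) {
    y <- ebes[[e]]
    aic0 <- AIC(lm(y ~ 1))
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      if (!is.numeric(x) || anyNA(x)) next
      if (length(unique(x)) < 2) {
        message("covariate ", cv, " is constant; skipped")
        next
      }
      drops <- c(linear = aic0 - AIC(lm(y ~ x)))
      if (all(x > 0)) drops["log"] <- aic0 - AIC(lm(y ~ log(x)))
      best <- which.max(drops)
      out[[length(out) + 1L]] <- data.frame(
        eta = e, covariate = cv, basis = names(drops)[best],
        aic_drop = unname(drops[best]),
        retained = unname(drops[best]) >= cutoff)
    }
  }
  res <- do.call(rbind, out)
  res[order(-res$aic_drop), ]
}

#' Standard errors from a central-difference Hessian
#'
#' Computes the Hessian of `fn` (one half the objective-function value,
#' i.e. the negative log-likelihood) at `par` by central differences,
#' inverts it as the asymptotic covariance and returns standard errors.
#' A non-positive-definite Hessian is flagged and no SEs are returned.
#'
#' @param fn function of the natural-scale parameter vector returning
#'   -log-likelihood (OFV/2)
#' @param par parameter vector at the optimum
#' @param rel_step relative finite-difference step
#' @return list with `se`, `cov`, `hessian`, `ok`
#' @export
standard_errors <- function(fn, par, rel_step = 1e-3) {
  H <- fd_hessian(fn, par, rel_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || any(ev <= 0))
    return(list(se = NULL, cov = NULL, hessian = H, ok = FALSE))
  cv <- solve(H)
  list(se = sqrt(diag(cv)), cov = cv, hessian = H, ok = TRUE)
}

# first-order (KKT) optimality at a box-constrained optimum: interior
# coordinates need a small gradient; bound-active ones a gradient pointing
# outward.  nlminb's "false convergence (8)" at active variance bounds is
# routinely a true optimum, so the code alone is not trusted.
kkt_ok <- function(obj, par, lower, upper, tol = 2, h = 1e-4) {
  g <- numeric(length(par))
  for (j in seq_along(par)) {
    xp <- par; xp[j] <- par[j] + h
    xm <- par; xm[j] <- par[j] - h
    g[j] <- (obj(xp) - obj(xm)) / (2 * h)
  }
  at_lo <- par <= lower + 1e-6
  at_hi <- par >= upper - 1e-6
  all(ifelse(at_lo, g > -tol, ifelse(at_hi, g < tol, abs(g) < tol)))
}

fd_hessian <- function(fn, x, rel = 1e-3) {
  k <- length(x)
  h <- rel * (abs(x) + rel)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  for (j in seq_len(k)) {
    xp <- x; xp[j] <- x[j] + h[j]; fp <- fn(xp)
    xm <- x; xm[j] <- x[j] - h[j]; fm <- fn(xm)
    H[j, j] <- (fp - 2 * f0 + fm) / h[j]^2
  }
  if (k > 1) for (j in 1:(k - 1)) for (l in (j + 1):k) {
    xx <- x
    xx[j] <- x[j] + h[j]; xx[l] <- x[l] + h[l]; fpp <- fn(xx)
    xx[l] <- x[l] - h[l]; fpm <- fn(xx)
    xx[j] <- x[j] - h[j]; xx[l] <- x[l] + h[l]; fmp <- fn(xx)
    xx[l] <- x[l] - h[l]; fmm <- fn(xx)
    H[j, l] <- H[l, j] <- (fpp - fpm - fmp + fmm) / (4 * h[j] * h[l])
  }
  0.5 * (H + t(H))
}

#' Eta shrinkage
#'
#' 100 * (1 - SD(eta-hat) / sqrt(omega^2)), SD with the n-1 denominator.
#' EBEs collapse toward zero (shrinkage toward 100\%) when the individual
#' data carry little information about a random effect.
#'
#' @param ebes vector of empirical Bayes eta estimates (>= 2 subjects)
#' @param omega_sq the estimated BSV variance (> 0)
#' @return shrinkage in percent
#' @examples
#' shrinkage(c(0, 0, 0, 0), 0.1)  # 100
#' @export
shrinkage <- function(ebes, omega_sq) {
  if (length(ebes) < 2) stop("need >= 2 subjects")
  if (omega_sq <= 0) stop("omega_sq must be > 0")
  100 * (1 - sd(ebes) / sqrt(omega_sq))
}
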