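#' Visual predictive check
#'
#' Simulates `n_rep` replicate virtual trials at the final PK estimates
#' (between-subject variability plus residual error, on the observed
#' design: each subject's own weight, regimen and nominal sampling times)
#' and summarises the simulated concentrations by the 5th, 50th and 95th
#' percentile at every nominal time, for overlay on the observations.
#' No binning is applied since the design is fixed-time.
#'
#' @param fit a PK [fit_population()] result
#' @param data the [pkpd_dataset()] that was fitted
#' @param n_rep number of replicate trials (default 1000)
#' @param seed RNG seed
#' @return object of class `"vpc_result"`: list with `bands` (time, p5,
#'   p50, p95) and `observed` (time, conc)
#' @export
vpc <- function(fit, data, n_rep = 1000, seed = 1) {
  stopifnot(inherits(fit, "htb_fit"), fit$endpoint == "pk", n_rep >= 1)
  nat <- fit$estimates
  th <- fit_theta_pk(fit)
  om2 <- nat[c("omega2_cl", "omega2_v", "omega2_kf")]
  sg <- sigma_model(fit$model$error, prop2 = nat[["sigma_prop2"]],
                    add2 = nat[["sigma_add2"]])
  ids <- data$subjects$id
  sims <- with_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      out_t <- out_c <- numeric(0)
      for (i in seq_along(ids)) {
        pk <- data$pk[data$pk$id == ids[i], , drop = FALSE]
        if (!nrow(pk)) next
        reg <- subject_regimen(data, ids[i])
        eta <- rnorm(3) * sqrt(om2)
        p <- individual_params(th, data$subjects$weight[i], eta)
        f <- concentration(reg, pk$time, p)
        y <- f * (1 + rnorm(length(f)) * sqrt(sg$prop2)) +
          rnorm(length(f)) * sqrt(sg$add2)
        out_t <- c(out_t, pk$time); out_c <- c(out_c, pmax(y, 0))
      }
      data.frame(time = out_t, conc = out_c)
    })
  })
  all <- do.call(rbind, sims)
  qs <- aggregate(conc ~ time, all, quantile, probs = c(0.05, 0.5, 0.95))
  bands <- data.frame(time = qs$time, p5 = qs$conc[, 1], p50 = qs$conc[, 2],
                      p95 = qs$conc[, 3])
  structure(list(bands = bands[order(bands$time), ],
                 observed = data$pk[, c("time", "conc")],
                 n_rep = n_rep, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("<vpc_result>", x$n_rep, "replicates\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

# theta_pk object from a PK fit's estimates and covariate structure
fit_theta_pk <- function(fit) {
  nat <- fit$estimates
  theta_pk(nat[["theta1"]], nat[["theta2"]], nat[["theta3"]],
           wt_cl = if (fit$model$covariate == "power") nat[["theta4"]] else 0,
           wt_v = if (fit$model$covariate == "power") 1 else 0,
           ref_weight = fit$model$ref_weight)
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples whole subjects with replacement to the original n, refits
#' each replicate dataset (initialised at the point estimates) and
#' reports the median and 95\% percentile confidence interval of every
#' estimated parameter over the successful replicates.  When `pd_model`
#' is supplied the PD model is refit sequentially on each replicate as
#' well.  Failed replicates are counted and excluded; more than 50\%
#' failures flags the result unreliable.
#'
#' @param data a [pkpd_dataset()]
#' @param model a [pk_model_spec()]
#' @param n_rep replicates (default 1000)
#' @param seed RNG seed for resampling
#' @param init initial values for the replicate fits (defaults to the
#'   original-data fit's estimates)
#' @param pd_model optionally a [pd_model_spec()] to bootstrap the PD
#'   parameters too
#' @return object of class `"bootstrap_result"`: `summary` data frame
#'   (parameter, median, lower, upper), `n_failed`, `unreliable`
#' @export
bootstrap_model <- function(data, model = pk_model_spec(), n_rep = 1000,
                            seed = 1, init = NULL, pd_model = NULL) {
  stopifnot(n_rep >= 1)
  base_fit <- fit_population(data, model, init = init, seed = seed,
                             compute_se = FALSE)
  init_rep <- as.list(base_fit$estimates[base_fit$estimated])
  base_pd <- if (!is.null(pd_model))
    fit_pd_sequential(data, base_fit, pd_model, compute_se = FALSE)
  ids <- data$subjects$id
  n <- length(ids)
  draws <- with_seed(seed, replicate(n_rep, sample(ids, n, replace = TRUE),
                                     simplify = FALSE))
  reps <- list()
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    boot <- resample_dataset(data, draws[[r]])
    est <- try({
      f <- fit_population(boot, model, init = init_rep,
                          seed = child_seed(seed, r), compute_se = FALSE)
      if (!f$convergence$ok) stop("replicate fit did not converge")
      e <- f$estimates[f$estimated]
      if (!is.null(pd_model)) {
        fp <- fit_pd_sequential(boot, f, pd_model,
                                init = as.list(base_pd$estimates[base_pd$estimated]),
                                compute_se = FALSE)
        e <- c(e, fp$estimates[fp$estimated])
      }
      e
    }, silent = TRUE)
    if (inherits(est, "try-error")) n_failed <- n_failed + 1L
    else reps[[length(reps) + 1L]] <- est
  }
  if (!length(reps)) stop("all bootstrap replicates failed")
  mat <- do.call(rbind, reps)
  summary <- data.frame(
    parameter = colnames(mat),
    median = apply(mat, 2, median),
    lower = apply(mat, 2, quantile, 0.025),
    upper = apply(mat, 2, quantile, 0.975), row.names = NULL)
  structure(list(summary = summary, n_failed = n_failed, n_rep = n_rep,
                 unreliable = n_failed > n_rep / 2, estimates = mat),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$n_rep, "replicates,", x$n_failed, "failed",
      if (x$unreliable) "(UNRELIABLE: >50% failures)", "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# subjects resampled with replacement get fresh ids 1..n
resample_dataset <- function(data, drawn_ids) {
  sub <- dose <- pk <- pd <- list()
  for (k in seq_along(drawn_ids)) {
    id <- drawn_ids[k]
    s <- data$subjects[data$subjects$id == id, , drop = FALSE]
    s$id <- k
    d <- data$doses[data$doses$id == id, , drop = FALSE]
    p1 <- data$pk[data$pk$id == id, , drop = FALSE]
    p2 <- data$pd[data$pd$id == id, , drop = FALSE]
    d$id <- rep(k, nrow(d)); p1$id <- rep(k, nrow(p1))
    p2$id <- rep(k, nrow(p2))
    sub[[k]] <- s; dose[[k]] <- d; pk[[k]] <- p1; pd[[k]] <- p2
  }
  pkpd_dataset(do.call(rbind, sub), do.call(rbind, dose),
               do.call(rbind, pk), do.call(rbind, pd))
}

#' Steady-state pre-dose trough concentration
#'
#' Closed-form trough of the one-compartment first-order-input model under
#' repeated dosing of `dose` mg every `tau` h for the typical subject at
#' the reference weight:
#' Css,min = (D/V) * kf/(kf-ke) * (s_ke/(1-s_ke) - s_kf/(1-s_kf)) with
#' s_k = exp(-k tau) and ke = CL/V; the kf = ke degeneracy uses the limit
#' (D/V) * ke * tau * s/(1-s)^2.
#'
#' @param theta a [theta_pk()]
#' @param dose maintenance dose (mg)
#' @param tau dosing interval (h)
#' @return trough concentration (ug/mL)
#' @examples
#' css_min(theta_pk(0.2, 8.3, 0.341))  # about 99.4
#' @export
css_min <- function(theta, dose = 600, tau = 24) {
  stopifnot(inherits(theta, "theta_pk"), tau > 0, dose > 0)
  ke <- theta$cl / theta$v
  kf <- theta$kf
  if (ke * tau < 1e-10)
    stop("ke * tau below floor: accumulation diverges, no steady state")
  s_ke <- exp(-ke * tau)
  if (abs(kf - ke) <= 1e-8 * ke)
    return(dose / theta$v * ke * tau * s_ke / (1 - s_ke)^2)
  s_kf <- exp(-kf * tau)
  dose / theta$v * kf / (kf - ke) *
    (s_ke / (1 - s_ke) - s_kf / (1 - s_kf))
}

#' Accumulation factor of repeated dosing
#'
#' R = 1 / (1 - exp(-ke tau)), the ratio of steady-state to single-dose
#' exposure for dosing every `tau` hours with elimination rate `ke`.
#'
#' @param ke elimination rate constant (1/h, > 0)
#' @param tau dosing interval (h, > 0)
#' @return accumulation ratio (>= 1)
#' @examples
#' accumulation_factor(0.2 / 8.3, 24)  # about 2.28
#' @export
accumulation_factor <- function(ke, tau) {
  stopifnot(ke > 0, tau > 0)
  1 / (1 - exp(-ke * tau))
}

#' Observed and predicted IPA counts over time
#'
#' Per nominal PD sampling time: the number of subjects observed, the
#' observed count of inhibition (DV = 1), and the model-predicted count,
#' computed as round(sum of the per-subject Hill probabilities) at each
#' subject's individual (empirical-Bayes) predicted concentration and
#' individual EC50.  At the pre-dose time the concentration is 0, so the
#' predicted count is exactly 0.
#'
#' @param pd_fit a [fit_pd_sequential()] result
#' @param pk_fit the PK [fit_population()] result it was conditioned on
#' @param data the [pkpd_dataset()]
#' @return data frame with columns `time`, `n`, `observed`,
#'   `observed_pct`, `predicted`, `predicted_pct`
#' @export
ipa_table <- function(pd_fit, pk_fit, data) {
  stopifnot(inherits(pd_fit, "htb_fit"), pd_fit$endpoint == "pd",
            nrow(data$pd) > 0)
  ipk <- individual_pk_table(pk_fit)
  gamma <- pd_fit$estimates[["gamma"]]
  ec50_typ <- pd_fit$estimates[["ec50"]]
  times <- sort(unique(data$pd$time))
  out <- data.frame(time = times, n = 0L, observed = 0L,
                    observed_pct = 0, predicted = 0L, predicted_pct = 0)
  for (k in seq_along(times)) {
    rows <- data$pd[data$pd$time == times[k], , drop = FALSE]
    psum <- 0
    for (j in seq_len(nrow(rows))) {
      id <- rows$id[j]
      p <- ipk[ipk$id == id, ]
      cc <- concentration(subject_regimen(data, id), rows$time[j], p)
      ec50_i <- ec50_typ *
        exp(pd_fit$ebes[match(as.character(id), rownames(pd_fit$ebes)), 1])
      psum <- psum + prob_ipa(cc, ec50_i, gamma)
    }
    out$n[k] <- nrow(rows)
    out$observed[k] <- sum(rows$dv)
    out$predicted[k] <- as.integer(round(psum))
    out$observed_pct[k] <- round(100 * out$observed[k] / out$n[k])
    out$predicted_pct[k] <- round(100 * out$predicted[k] / out$n[k])
  }
  out
}

#' Goodness-of-fit residual table
#'
#' Per non-BLQ PK observation: the population prediction PRED (eta = 0),
#' the individual prediction IPRED (at the empirical Bayes eta), the
#' individual weighted residual IWRES = (obs - IPRED)/sd(IPRED), and the
#' conditional weighted residual CWRES from the first-order linearization
#' of the conditional model around eta-hat:
#' CWRES = V^{-1/2} (y - f(eta-hat) + G eta-hat), V = G Omega G' + W.
#'
#' @param fit a converged PK [fit_population()] result
#' @param data the fitted [pkpd_dataset()]
#' @return data frame with `id`, `time`, `obs`, `pred`, `ipred`, `iwres`,
#'   `cwres`; rows with IPRED = 0 carry NA residuals and are flagged in
#'   the `flagged` attribute
#' @export
gof <- function(fit, data) {
  stopifnot(inherits(fit, "htb_fit"), fit$endpoint == "pk")
  nat <- fit$estimates
  th <- fit_theta_pk(fit)
  om2 <- diag(nat[c("omega2_cl", "omega2_v", "omega2_kf")], 3)
  sp2 <- nat[["sigma_prop2"]]; sa2 <- nat[["sigma_add2"]]
  out <- list()
  flagged <- 0L
  for (i in seq_len(nrow(data$subjects))) {
    id <- data$subjects$id[i]
    pk <- data$pk[data$pk$id == id & !data$pk$blq, , drop = FALSE]
    if (!nrow(pk)) next
    reg <- subject_regimen(data, id)
    w <- data$subjects$weight[i]
    eta <- fit$ebes[match(as.character(id), rownames(fit$ebes)), ]
    f0 <- concentration(reg, pk$time, individual_params(th, w, c(0, 0, 0)))
    fh <- concentration(reg, pk$time, individual_params(th, w, eta))
    wv <- sp2 * fh^2 + sa2
    iwres <- ifelse(fh > 0 & wv > 0, (pk$conc - fh) / sqrt(wv), NA_real_)
    flagged <- flagged + sum(fh <= 0 | wv <= 0)
    # finite-difference d f / d eta at eta-hat
    G <- matrix(0, nrow(pk), 3)
    h <- 1e-4
    for (j in 1:3) {
      ep <- eta; ep[j] <- eta[j] + h
      em <- eta; em[j] <- eta[j] - h
      G[, j] <- (concentration(reg, pk$time, individual_params(th, w, ep)) -
                 concentration(reg, pk$time, individual_params(th, w, em))) /
        (2 * h)
    }
    V <- G %*% om2 %*% t(G) + diag(wv, nrow(pk))
    cw <- tryCatch(
      backsolve(chol(V), pk$conc - fh + as.numeric(G %*% eta),
                transpose = TRUE),
      error = function(e) rep(NA_real_, nrow(pk)))
    out[[length(out) + 1L]] <- data.frame(
      id = id, time = pk$time, obs = pk$conc, pred = f0, ipred = fh,
      iwres = iwres, cwres = cw)
  }
  res <- do.call(rbind, out)
  attr(res, "flagged") <- flagged
  res
}
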