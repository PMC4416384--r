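#' Dichotomize platelet aggregation at the 74% threshold
#'
#' Maximal \% platelet aggregation (light-transmission aggregometry) above
#' 74\% is classed as no inhibition (DV = 0); values at or below 74\% as
#' inhibition of platelet aggregation, IPA (DV = 1).
#'
#' @param aggregation \% aggregation in [0, 100] (vectorized)
#' @return integer vector of 0/1
#' @examples
#' binarize(c(85, 30, 74))  # 0 1 1
#' @export
binarize <- function(aggregation) {
  if (any(!is.finite(aggregation)) || any(aggregation < 0) ||
      any(aggregation > 100))
    stop("aggregation must be within [0, 100]")
  as.integer(aggregation <= 74)
}

#' Probability of inhibition of platelet aggregation (Hill model)
#'
#' P(IPA | C) = C^gamma / (C^gamma + EC50^gamma), evaluated on the logit
#' scale as plogis(gamma * (log C - log EC50)) so that large shape factors
#' (the fitted gamma is about 19, a nearly quantal concentration-response)
#' do not overflow.  C = 0 maps to probability 0.
#'
#' @param c concentration (ug/mL, >= 0, vectorized)
#' @param ec50 concentration of half-maximal inhibition probability (> 0)
#' @param gamma Hill shape factor (> 0)
#' @return probabilities in [0, 1], monotone non-decreasing in `c`
#' @examples
#' prob_ipa(84.9, 84.9, 19.2)  # 0.5
#' @export
prob_ipa <- function(c, ec50, gamma) {
  stopifnot(ec50 > 0, gamma > 0)
  if (any(c < 0)) stop("concentration must be >= 0")
  p <- numeric(length(c))
  pos <- c > 0
  p[pos] <- plogis(gamma * (log(c[pos]) - log(ec50)))
  p
}

#' Bernoulli log-likelihood of a binary PD observation
#'
#' dv * log(p) + (1 - dv) * log(1 - p) with p clamped to
#' [1e-10, 1 - 1e-10].
#'
#' @param dv binary outcome (0/1, vectorized)
#' @param p model probability in [0, 1]
#' @return log-density
#' @export
pd_loglik_contrib <- function(dv, p) {
  if (any(p < 0) || any(p > 1)) stop("p must be within [0, 1]")
  if (!all(dv %in% c(0, 1))) stop("dv must be 0 or 1")
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  dv * log(p) + (1 - dv) * log(1 - p)
}

#' Logistic-regression initialization of the binary PD model
#'
#' Fits logit P(DV = 1) = beta0 + beta1 * log(C) by maximum likelihood and
#' maps the coefficients onto Hill-model initial values
#' EC50 = exp(-beta0/beta1), gamma = beta1 (with log-concentration as the
#' regressor the logit-linear model *is* the logit of the Hill model).
#' Input is either raw binary rows (`conc`, `dv`) or a per-time frequency
#' table (`conc` = representative concentration, `freq` = observed
#' frequency of DV = 1, `n` = subjects per time).  Rows with C = 0 carry no
#' information about the log-linear slope and are dropped with a note.
#' On complete separation the fit is repeated with two half-weight
#' pseudo-observations (one of each outcome) at the mean log-concentration
#' and the result flagged.
#'
#' @param conc concentrations (ug/mL)
#' @param dv binary outcomes, same length as `conc` (omit when using
#'   `freq`)
#' @param freq per-time frequencies of DV = 1 in [0, 1]
#' @param n number of subjects behind each frequency (default 34)
#' @return list with `beta0`, `beta1`, `ec50`, `gamma`, `separation`
#'   (logical), `degenerate` (logical; slope indistinguishable from 0)
#' @examples
#' co <- c(20, 50, 80, 90, 120, 150)
#' p <- prob_ipa(co, 84.9, 19.2)
#' logistic_init(conc = co, freq = p, n = 100)
#' @export
logistic_init <- function(conc, dv = NULL, freq = NULL, n = 34) {
  stopifnot(is.null(dv) != is.null(freq))
  keep <- conc > 0
  if (!all(keep)) message("dropping ", sum(!keep),
                          " zero-concentration rows from logistic init")
  x <- log(conc[keep])
  if (!is.null(freq)) {
    freq <- freq[keep]
    if (length(x) < 2) stop("need >= 2 usable concentration points")
    succ <- freq * n
    y <- cbind(succ, n - succ)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    all0 <- all(freq <= 0); all1 <- all(freq >= 1)
  } else {
    dv <- dv[keep]
    if (length(x) < 2) stop("need >= 2 usable concentration points")
    fit <- suppressWarnings(glm(dv ~ x, family = binomial()))
    all0 <- all(dv == 0); all1 <- all(dv == 1)
  }
  co <- coef(fit)
  # complete separation inflates the slope without bound (the Hill shape
  # factor is bounded at 100 downstream, so 150 is safely beyond it)
  separation <- all0 || all1 || !fit$converged ||
    abs(co[2]) > 150 || any(!is.finite(co))
  if (separation) {
    # penalized fallback: half-weight pseudo-observations of each outcome
    xm <- mean(x)
    yv <- if (!is.null(freq)) c(freq, 0, 1) else c(dv, 0, 1)
    wv <- c(rep(if (!is.null(freq)) n else 1, length(x)), 0.5, 0.5)
    fit <- suppressWarnings(glm(yv ~ c(x, xm, xm), weights = wv,
                                family = binomial()))
    co <- coef(fit)
  }
  beta0 <- unname(co[1]); beta1 <- unname(co[2])
  degenerate <- is.na(beta1) || abs(beta1) < 1e-6
  ec50 <- if (degenerate) NA_real_ else exp(-beta0 / beta1)
  list(beta0 = beta0, beta1 = beta1, ec50 = ec50, gamma = beta1,
       separation = separation, degenerate = degenerate)
}

#' Turnover (indirect response) parameters and simulator
#'
#' The inhibition-of-build-up alternative PD model:
#' dR/dt = kin * (1 - Imax * C/(IC50 + C)) - kout * R, where R is the
#' continuous aggregation response, kin the production rate, kout the
#' first-order loss rate, Imax the maximal fractional inhibition and IC50
#' the concentration of half-maximal inhibition.  Kept as a
#' model-comparison alternative and simulator only; the binary probability
#' model is the estimation endpoint.
#'
#' @param kin,kout,ic50 positive rates/concentration
#' @param imax fraction in [0, 1]
#' @export
turnover_params <- function(kin, kout, imax, ic50) {
  stopifnot(kin > 0, kout > 0, ic50 > 0, imax >= 0, imax <= 1)
  structure(list(kin = kin, kout = kout, imax = imax, ic50 = ic50),
            class = "turnover_params")
}

#' @rdname turnover_params
#' @param p a [turnover_params()]
#' @param conc_fn function of time returning concentration (ug/mL)
#' @param r0 initial response (>= 0); `kin/kout` is the drug-free steady
#'   state
#' @param grid increasing time grid (h) at which to report the response
#' @param h_max maximal internal RK4 step (h)
#' @return numeric response trajectory on `grid`
#' @examples
#' p <- turnover_params(10, 0.1, 1, 50)
#' simulate_turnover(p, function(t) 0 * t, r0 = 100, grid = 0:10)
#' @export
simulate_turnover <- function(p, conc_fn, r0, grid, h_max = 0.05) {
  stopifnot(inherits(p, "turnover_params"), r0 >= 0)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  deriv <- function(t, r) {
    c_ <- conc_fn(t)
    p$kin * (1 - p$imax * c_ / (p$ic50 + c_)) - p$kout * r
  }
  out <- numeric(length(grid))
  r <- r0
  t <- grid[1]
  out[1] <- r0
  for (i in seq_along(grid)[-1]) {
    span <- grid[i] - t
    nstep <- max(1L, ceiling(span / h_max))
    h <- span / nstep
    for (s in seq_len(nstep)) {
      k1 <- deriv(t, r)
      k2 <- deriv(t + h / 2, r + h / 2 * k1)
      k3 <- deriv(t + h / 2, r + h / 2 * k2)
      k4 <- deriv(t + h, r + h * k3)
      r <- r + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    if (!is.finite(r)) stop("turnover integrator failed at t = ", t)
    out[i] <- r
  }
  out
}
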