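#' Configure a virtual trial
#'
#' The generator reproduces the statistical structure the analysis
#' assumes: n subjects with truncated-normal weights (mean 70.8 kg, SD
#' 9.0, bounds 53.3-89.7), the loading/maintenance regimen with 14 PK and
#' 10 PD nominal sampling times, lognormal between-subject variability
#' and proportional residual error at the final population estimates, and
#' a bimodal \% aggregation endpoint: a latent inhibition state drawn
#' from the Hill probability at the individual concentration, emitted as
#' a continuous \% aggregation from the inhibited mode (mean 30, SD 10,
#' truncated to [0, 74]) or the non-inhibited mode (mean 85, SD 5,
#' truncated to (74, 100]).  Modes must straddle the 74\% threshold so
#' that [binarize()] recovers the latent state exactly.
#'
#' @param n_subjects number of subjects (>= 1; study n is 34)
#' @param weight_mean,weight_sd,weight_bounds weight distribution (kg)
#' @param parameters simulation truth, as [default_parameters()]
#' @param design a [study_design()]-shaped list
#' @param agg_modes list with `inhibited` and `uninhibited`
#'   `c(mean =, sd =)` entries
#' @param seed master RNG seed; every downstream draw flows from it
#' @return list of class `"simulation_config"`
#' @export
simulation_config <- function(n_subjects = 34, weight_mean = 70.8,
                              weight_sd = 9.0,
                              weight_bounds = c(53.3, 89.7),
                              parameters = default_parameters(),
                              design = study_design(),
                              agg_modes = list(
                                inhibited = c(mean = 30, sd = 10),
                                uninhibited = c(mean = 85, sd = 5)),
                              seed = 1) {
  stopifnot(n_subjects >= 1, weight_bounds[1] <= weight_bounds[2])
  if (agg_modes$inhibited[["mean"]] > 74 ||
      agg_modes$uninhibited[["mean"]] <= 74)
    stop("aggregation modes must straddle the 74% threshold")
  structure(list(n_subjects = n_subjects, weight_mean = weight_mean,
                 weight_sd = weight_sd, weight_bounds = weight_bounds,
                 parameters = parameters, design = design,
                 agg_modes = agg_modes, seed = seed),
            class = "simulation_config")
}

# inverse-CDF truncated normal draws (consumes n uniforms)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) {
    runif(n)  # keep the RNG stream aligned
    return(rep(lo, n))
  }
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(runif(n, plo, phi)) * sd + mean
}

#' Sample subject weights
#'
#' Truncated-normal draws from the demographic weight distribution.
#'
#' @param n number of subjects
#' @param cfg a [simulation_config()]
#' @param seed RNG seed (default: the config's)
#' @return numeric vector of weights in kg, inside the truncation bounds
#' @export
sample_weights <- function(n, cfg = simulation_config(), seed = cfg$seed) {
  stopifnot(n >= 1)
  with_seed(seed, rtruncnorm(n, cfg$weight_mean, cfg$weight_sd,
                             cfg$weight_bounds[1], cfg$weight_bounds[2]))
}

#' Simulate a virtual trial
#'
#' Per subject: draw the PK random-effect vector, compute individual
#' parameters, generate PK observations as model concentration times
#' (1 + proportional error) floored at zero (values below the 1 ug/mL
#' LLOQ are flagged BLQ); draw the individual EC50, evaluate the Hill
#' probability at the noise-free individual concentration at each PD
#' time, draw the latent inhibition state Bernoulli(P), and emit the
#' continuous \% aggregation from the corresponding truncated mode along
#' with its binarized DV.  With the default design, n subjects yield
#' 14 n PK and 10 n PD records.
#'
#' @param cfg a [simulation_config()]
#' @return a [pkpd_dataset()]
#' @examples
#' d <- simulate_trial(simulation_config(n_subjects = 4, seed = 42))
#' nrow(d$pk)  # 56
#' @export
simulate_trial <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  par <- cfg$parameters
  th <- par$theta
  sg <- par$sigma
  reg <- cfg$design$regimen
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    weights <- rtruncnorm(n, cfg$weight_mean, cfg$weight_sd,
                          cfg$weight_bounds[1], cfg$weight_bounds[2])
    subjects <- data.frame(id = seq_len(n), weight = weights)
    doses <- pk <- pd <- list()
    for (i in seq_len(n)) {
      eta <- rnorm(3) * sqrt(par$omega2)
      p <- individual_params(th, weights[i], eta)
      f <- concentration(reg, cfg$design$pk_times, p)
      y <- f * (1 + rnorm(length(f)) * sqrt(sg$prop2)) +
        rnorm(length(f)) * sqrt(sg$add2)
      y <- pmax(y, 0)
      pk[[i]] <- data.frame(id = i, time = cfg$design$pk_times, conc = y,
                            blq = y < LLOQ)
      eta4 <- rnorm(1) * sqrt(par$omega2_ec50)
      ec50_i <- par$ec50 * exp(eta4)
      fpd <- concentration(reg, cfg$design$pd_times, p)
      prob <- prob_ipa(fpd, ec50_i, par$gamma)
      latent <- rbinom(length(prob), 1, prob)
      m_in <- cfg$agg_modes$inhibited
      m_un <- cfg$agg_modes$uninhibited
      agg <- ifelse(latent == 1,
                    rtruncnorm(length(prob), m_in[["mean"]], m_in[["sd"]],
                               0, 74),
                    rtruncnorm(length(prob), m_un[["mean"]], m_un[["sd"]],
                               74 + 1e-9, 100))
      pd[[i]] <- data.frame(id = i, time = cfg$design$pd_times,
                            dv = binarize(agg), agg = agg)
      doses[[i]] <- data.frame(id = i, time = reg$time, amount = reg$amount)
    }
    pkpd_dataset(subjects, do.call(rbind, doses), do.call(rbind, pk),
                 do.call(rbind, pd))
  })
}

#' Check for bimodality of the aggregation distribution
#'
#' Fits a two-component Gaussian mixture by EM and reports the component
#' means, the mixing fraction, Ashman's D separation statistic
#' (sqrt(2) |m1 - m2| / sqrt(s1^2 + s2^2); D > 2 indicates clear
#' bimodality) and whether the modes straddle the 74\% threshold.
#'
#' @param aggregations vector of \% aggregation values (>= 20)
#' @return list with `modes`, `sds`, `mixing` (fraction in the lower
#'   mode), `ashman_d`, `bimodal`, `straddles_74`, `frac_near_74`
#'   (fraction within 5 points of the threshold)
#' @export
bimodality_check <- function(aggregations) {
  x <- aggregations[is.finite(aggregations)]
  if (length(x) < 20) stop("need >= 20 values")
  # EM for a 2-component normal mixture, split-at-median start
  mu <- c(mean(x[x <= median(x)]), mean(x[x > median(x)]))
  s2 <- rep(max(var(x) / 4, 1e-2), 2)
  lam <- 0.5
  for (it in 1:200) {
    d1 <- lam * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- (1 - lam) * stats::dnorm(x, mu[2], sqrt(s2[2]))
    z <- d1 / pmax(d1 + d2, 1e-300)
    lam_new <- mean(z)
    mu_new <- c(sum(z * x) / sum(z), sum((1 - z) * x) / sum(1 - z))
    s2_new <- c(sum(z * (x - mu_new[1])^2) / sum(z),
                sum((1 - z) * (x - mu_new[2])^2) / sum(1 - z))
    s2_new <- pmax(s2_new, 1e-4)
    if (max(abs(mu_new - mu)) < 1e-8) {
      mu <- mu_new; s2 <- s2_new; lam <- lam_new
      break
    }
    mu <- mu_new; s2 <- s2_new; lam <- lam_new
  }
  ord <- order(mu)
  mu <- mu[ord]; s2 <- s2[ord]
  lam <- if (ord[1] == 1) lam else 1 - lam
  d_ash <- sqrt(2) * abs(diff(mu)) / sqrt(sum(s2))
  list(modes = mu, sds = sqrt(s2), mixing = lam, ashman_d = d_ash,
       bimodal = d_ash > 2,
       straddles_74 = mu[1] <= 74 && mu[2] > 74,
       frac_near_74 = mean(abs(x - 74) <= 5))
}
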