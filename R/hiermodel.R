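# Bayesian hierarchical models of pairing effects.
#
# Four models, all sampled with the adaptive Metropolis-within-Gibbs
# backend (see mcmc.R); priors are centred on the null hypothesis and
# scaled from the solo data (effects ~ N(0, SD_solo), population mean ~
# N(mean_solo, SD_solo), scale parameters ~ half-N(sqrt(SD_solo))).
#
# 1. fit_pair_model      flight medians; the pairing / mixing-weight model
# 2. fit_spacing_model   sampled wingbeats; pairing intercept at 0 m +
#                        per-metre spacing slope + per-flight effect
#                        (marginalised, compound-symmetry likelihood)
# 3. fit_coupling_model  behind-bird on front-bird median frequency
# 4. fit_leadership_model Bernoulli regression of who leads

default_covariates <- function(summaries, response) {
  cand <- c("airspeed", "wind_support", "crosswind", "temp_c",
            "humidity_pct", "rho_air")
  if (response %in% c("airspeed", "airspeed_ms")) {
    cand <- setdiff(cand, "airspeed")
  }
  intersect(cand, names(summaries))
}

# continuous covariate matrix (centred) plus sum-to-zero date dummies
build_design <- function(summaries, covariates) {
  X <- NULL
  nm <- character(0)
  for (v in covariates) {
    X <- cbind(X, summaries[[v]] - mean(summaries[[v]]))
    nm <- c(nm, v)
  }
  if ("date" %in% names(summaries) &&
      length(unique(summaries$date)) > 1) {
    d <- factor(summaries$date)
    L <- nlevels(d)
    M <- stats::model.matrix(~ d - 1)
    # sum-to-zero: L-1 free columns, last level = -(sum of the others)
    Z <- M[, -L, drop = FALSE] - M[, L]
    X <- cbind(X, Z)
    nm <- c(nm, paste0("date_", levels(d)[-L]))
  }
  if (is.null(X)) X <- matrix(0, nrow(summaries), 0)
  colnames(X) <- nm
  X
}

half_normal_lp <- function(x, scale) {
  stats::dnorm(x, 0, scale, log = TRUE) + log(2)
}

#' Fit the hierarchical pairing model to flight medians
#'
#' Response for flight of bird i (paired with j, or solo):
#' solo rows \eqn{y \sim N(\mu_i + \gamma X, \sigma)}; paired rows
#' \eqn{y \sim N(\delta_0 + \delta_1 |T_i - T_j| + \omega_i \mu_i +
#' (1 - \omega_i) \mu_j + \gamma X, \sigma)} with mixing weight
#' \eqn{\omega_i = \mathrm{logit}^{-1}(\eta_1 + \eta |T_i - T_j|)}.
#' Per-bird solo means are hierarchical, \eqn{\mu_i \sim N(\mu_0,
#' \tau_\mu)}. Priors are centred on the null with scales from the solo
#' rows of the response. Continuous covariates are centred; a `date`
#' column, if present, enters as sum-to-zero categories. Airspeed is
#' included as a covariate except when it is itself the response.
#'
#' @param summaries flight-summary data.frame with columns `bird_id`,
#'   `partner_id`, `is_pair` (0/1), `tarsus_diff_mm`, the response
#'   column, and any covariate columns.
#' @param response name of the response column (default `"freq_hz"`).
#' @param covariates covariate column names; default: the standard
#'   weather/airspeed set intersected with available columns.
#' @param priors optional named list overriding prior scales:
#'   `effect_sd`, `mu_mean`, `mu_sd`, `scale_sd`, `eta_sd`.
#' @param chains,warmup,iter MCMC budget (defaults 4 x 2000 + 2000; the
#'   full-accounting budget of 8 x 12500 + 12500 is configurable).
#' @param seed integer seed.
#' @return a `posterior_summary`; parameters `delta0`, `delta1`,
#'   `eta1`, `eta_s`, `mu[<bird>]`, `mu_pop_mean`, `mu_pop_sd`,
#'   `sigma`, `gamma[<covariate>]`.
#' @export
fit_pair_model <- function(summaries, response = "freq_hz",
                           covariates = NULL, priors = NULL,
                           chains = 4, warmup = 2000, iter = 2000,
                           seed = 1L) {
  if (!response %in% names(summaries)) {
    stop("response column '", response, "' not found")
  }
  if (is.null(covariates)) {
    covariates <- default_covariates(summaries, response)
  }
  mdl <- pair_model_data(summaries, response, covariates, priors)
  notes <- character(0)
  if (!any(mdl$is_pair)) {
    notes <- c(notes, "no paired rows: delta/eta parameters follow the prior")
  }
  fit <- amwg_sample(mdl$log_post, mdl$init, n_chains = chains,
                     warmup = warmup, iter = iter, seed = seed)
  draws <- transform_draws(fit$draws, mdl$positive)
  new_posterior(draws, fit$accept, paste0("pair_model[", response, "]"),
                notes)
}

# data, priors, initial values and log posterior for the pairing model;
# kept separate so the likelihood can be checked on its own
pair_model_data <- function(summaries, response, covariates, priors) {
  y <- summaries[[response]]
  is_pair <- summaries$is_pair == 1
  if (sum(!is_pair) < 2) stop("need at least 2 solo flights")
  birds <- sort(unique(summaries$bird_id))
  if (length(unique(summaries$bird_id[!is_pair])) < 2) {
    stop("need solo flights from at least 2 birds")
  }
  i_idx <- match(summaries$bird_id, birds)
  j_idx <- match(summaries$partner_id, birds)
  j_idx[!is_pair | is.na(j_idx)] <- i_idx[!is_pair | is.na(j_idx)]
  dT <- ifelse(is_pair, summaries$tarsus_diff_mm, 0)
  dT[is.na(dT)] <- 0
  X <- build_design(summaries, covariates)
  k <- ncol(X)

  solo_y <- y[!is_pair]
  m0 <- mean(solo_y)
  s0 <- stats::sd(solo_y)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  pr <- list(effect_sd = s0, mu_mean = m0, mu_sd = s0,
             scale_sd = sqrt(s0), eta_sd = 1.5)
  pr[names(priors)] <- priors

  B <- length(birds)
  pn <- c("delta0", "delta1", "eta1", "eta_s", paste0("mu[", birds, "]"),
          "mu_pop_mean", "mu_pop_sd", "sigma",
          if (k) paste0("gamma[", colnames(X), "]"))
  positive <- pn %in% c("mu_pop_sd", "sigma")
  mu_solo <- vapply(birds, function(b) {
    v <- y[!is_pair & summaries$bird_id == b]
    if (length(v)) mean(v) else m0
  }, numeric(1))
  init <- c(0, 0, 0, 0, mu_solo, m0, log(max(s0 / 2, 1e-3)),
            log(max(s0, 1e-3)), rep(0, k))
  names(init) <- pn
  mu_slice <- 4 + seq_len(B)
  g_slice <- if (k) 4 + B + 3 + seq_len(k) else integer(0)

  log_lik <- function(par) {
    mu <- par[mu_slice]
    sigma <- exp(par[4 + B + 3])
    om <- stats::plogis(par[3] + par[4] * dT)
    om[!is_pair] <- 1
    eta_lin <- if (k) as.numeric(X %*% par[g_slice]) else 0
    m <- is_pair * (par[1] + par[2] * dT) +
      om * mu[i_idx] + (1 - om) * mu[j_idx] + eta_lin
    sum(stats::dnorm(y, m, sigma, log = TRUE))
  }
  log_post <- function(par) {
    mu <- par[mu_slice]
    mu_mean <- par[4 + B + 1]
    mu_sd <- exp(par[4 + B + 2])
    sigma <- exp(par[4 + B + 3])
    lp <- log_lik(par) +
      stats::dnorm(par[1], 0, pr$effect_sd, log = TRUE) +
      stats::dnorm(par[2], 0, pr$effect_sd, log = TRUE) +
      stats::dnorm(par[3], 0, pr$eta_sd, log = TRUE) +
      stats::dnorm(par[4], 0, pr$eta_sd, log = TRUE) +
      sum(stats::dnorm(mu, mu_mean, mu_sd, log = TRUE)) +
      stats::dnorm(mu_mean, pr$mu_mean, pr$mu_sd, log = TRUE) +
      half_normal_lp(mu_sd, pr$scale_sd) + par[4 + B + 2] +
      half_normal_lp(sigma, pr$scale_sd) + par[4 + B + 3]
    if (k) lp <- lp + sum(stats::dnorm(par[g_slice], 0, pr$effect_sd,
                                       log = TRUE))
    lp
  }
  list(log_post = log_post, log_lik = log_lik, init = init,
       positive = positive, is_pair = is_pair, birds = birds)
}

# exponentiate log-scale (positive) parameters back to natural scale
transform_draws <- function(draws, positive) {
  for (j in which(positive)) draws[, j, ] <- exp(draws[, j, ])
  draws
}

#' Fit the wingbeat-level spacing model
#'
#' Per-wingbeat frequency model: \eqn{y = \beta_0 + \delta_{0m}
#' 1_{pair} + s \cdot d + b_{flight} + \epsilon}, where d is horizontal
#' spacing (m, paired wingbeats only), \eqn{\delta_{0m}} the pairing
#' effect at 0 m, s the per-metre slope, and \eqn{b_{flight} \sim N(0,
#' \tau)} a per-flight effect accounting for the repeated wingbeats
#' sampled from one flight. The flight effects are marginalised
#' analytically (compound-symmetry covariance per flight), so the
#' sampler runs over the fixed effects and the two scales only.
#'
#' @param wingbeats data.frame with `flight_id`, `is_pair` (0/1),
#'   `spacing_m` (NA for solo), `freq_hz` (or `response`).
#' @param response response column name (default `"freq_hz"`).
#' @param priors optional overrides (`effect_sd`, `mu_mean`, `mu_sd`,
#'   `scale_sd`).
#' @param chains,warmup,iter,seed MCMC budget and seed.
#' @return a `posterior_summary`; parameters `intercept_solo`,
#'   `delta_0m` (pairing effect at zero spacing), `slope`
#'   (Hz per metre), `tau_flight`, `sigma`.
#' @export
fit_spacing_model <- function(wingbeats, response = "freq_hz",
                              priors = NULL, chains = 4, warmup = 2000,
                              iter = 2000, seed = 1L) {
  y <- wingbeats[[response]]
  is_pair <- as.numeric(wingbeats$is_pair == 1)
  sp <- ifelse(is_pair == 1, wingbeats$spacing_m, 0)
  if (any(is.na(sp))) stop("paired wingbeats must carry spacing_m")
  fl <- factor(wingbeats$flight_id)
  nf <- tabulate(fl)
  solo_y <- y[is_pair == 0]
  m0 <- mean(solo_y)
  s0 <- stats::sd(solo_y)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  pr <- list(effect_sd = s0, mu_mean = m0, mu_sd = s0, scale_sd = sqrt(s0))
  pr[names(priors)] <- priors

  pn <- c("intercept_solo", "delta_0m", "slope", "tau_flight", "sigma")
  init <- c(m0, 0, 0, log(max(s0 / 2, 1e-3)), log(max(s0, 1e-3)))
  names(init) <- pn
  positive <- pn %in% c("tau_flight", "sigma")

  log_post <- function(par) {
    tau2 <- exp(2 * par[4])
    sig2 <- exp(2 * par[5])
    r <- y - (par[1] + par[2] * is_pair + par[3] * sp)
    sum_r <- rowsum(r, fl)
    sum_r2 <- rowsum(r * r, fl)
    rbar <- sum_r / nf
    ssw <- sum_r2 - nf * rbar^2
    ll <- -0.5 * sum((nf - 1) * log(2 * pi * sig2) +
                       log(2 * pi * (sig2 + nf * tau2)) +
                       ssw / sig2 +
                       nf * rbar^2 / (sig2 + nf * tau2))
    ll +
      stats::dnorm(par[1], pr$mu_mean, pr$mu_sd, log = TRUE) +
      stats::dnorm(par[2], 0, pr$effect_sd, log = TRUE) +
      stats::dnorm(par[3], 0, pr$effect_sd, log = TRUE) +
      half_normal_lp(exp(par[4]), pr$scale_sd) + par[4] +
      half_normal_lp(exp(par[5]), pr$scale_sd) + par[5]
  }
  fit <- amwg_sample(log_post, init, n_chains = chains, warmup = warmup,
                     iter = iter, seed = seed)
  draws <- transform_draws(fit$draws, positive)
  new_posterior(draws, fit$accept, "spacing_model")
}

#' Predicted pairing effect at a given spacing
#'
#' Linear-predictor identity: effect at distance d = `delta_0m` +
#' d * `slope`, evaluated on the posterior draws.
#'
#' @param posterior a `posterior_summary` from [fit_spacing_model()].
#' @param spacing_m horizontal spacing, metres.
#' @return data.frame with `mean`, `q2.5`, `q97.5` of the effect.
#' @export
spacing_effect_at <- function(posterior, spacing_m) {
  x <- posterior_draws(posterior, "delta_0m") +
    spacing_m * posterior_draws(posterior, "slope")
  qs <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  data.frame(mean = mean(x), q2.5 = qs[1], q97.5 = qs[2])
}

#' Fit the front-back frequency coupling model
#'
#' Regression of the behind bird's median wingbeat frequency on the
#' front bird's, \eqn{\bar W_B \sim N(\alpha_P + \beta_P \bar W_F +
#' \gamma X, \sigma')}, with per-pair intercepts and slopes partially
#' pooled around population means. A pooled slope of 1 corresponds to a
#' direct correlation of the pair's wingbeat frequencies; 0 to none.
#' The front frequency is centred, which affects the intercepts only.
#'
#' @param pair_medians data.frame with `pair_id`, `freq_front`,
#'   `freq_behind`, plus optional covariate columns.
#' @param covariates covariate column names (default none).
#' @param chains,warmup,iter,seed MCMC budget and seed.
#' @return a `posterior_summary`; pooled parameters `alpha`, `beta`,
#'   scales `tau_alpha`, `tau_beta`, `sigma`, and per-pair
#'   `alpha[<pair>]`, `beta[<pair>]`.
#' @export
fit_coupling_model <- function(pair_medians, covariates = character(0),
                               chains = 4, warmup = 2000, iter = 2000,
                               seed = 1L) {
  pairs <- sort(unique(pair_medians$pair_id))
  if (length(pairs) < 2) stop("need at least 2 pairs")
  if (any(tabulate(factor(pair_medians$pair_id)) < 2)) {
    warning("some pairs have a single flight; their slopes are ",
            "informed mainly by pooling")
  }
  p_idx <- match(pair_medians$pair_id, pairs)
  y <- pair_medians$freq_behind
  wf <- pair_medians$freq_front - mean(pair_medians$freq_front)
  X <- build_design(pair_medians, covariates)
  k <- ncol(X)
  m0 <- mean(y)
  s0 <- stats::sd(y)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  P <- length(pairs)
  pn <- c("alpha", "beta", "tau_alpha", "tau_beta", "sigma",
          paste0("alpha[", pairs, "]"), paste0("beta[", pairs, "]"),
          if (k) paste0("gamma[", colnames(X), "]"))
  init <- c(m0, 0, log(s0 / 2), log(0.3), log(max(s0, 1e-3)),
            rep(m0, P), rep(0, P), rep(0, k))
  names(init) <- pn
  positive <- pn %in% c("tau_alpha", "tau_beta", "sigma")
  a_slice <- 5 + seq_len(P)
  b_slice <- 5 + P + seq_len(P)
  g_slice <- if (k) 5 + 2 * P + seq_len(k) else integer(0)

  log_post <- function(par) {
    sigma <- exp(par[5])
    ta <- exp(par[3]); tb <- exp(par[4])
    m <- par[a_slice][p_idx] + par[b_slice][p_idx] * wf +
      (if (k) as.numeric(X %*% par[g_slice]) else 0)
    sum(stats::dnorm(y, m, sigma, log = TRUE)) +
      stats::dnorm(par[1], m0, s0, log = TRUE) +
      stats::dnorm(par[2], 0, 1, log = TRUE) +
      sum(stats::dnorm(par[a_slice], par[1], ta, log = TRUE)) +
      sum(stats::dnorm(par[b_slice], par[2], tb, log = TRUE)) +
      half_normal_lp(ta, sqrt(s0)) + par[3] +
      half_normal_lp(tb, 0.5) + par[4] +
      half_normal_lp(sigma, sqrt(s0)) + par[5] +
      (if (k) sum(stats::dnorm(par[g_slice], 0, s0, log = TRUE)) else 0)
  }
  fit <- amwg_sample(log_post, init, n_chains = chains, warmup = warmup,
                     iter = iter, seed = seed)
  draws <- transform_draws(fit$draws, positive)
  new_posterior(draws, fit$accept, "coupling_model")
}

#' Fit the Bernoulli leadership model
#'
#' Whether a given bird leads its pair, \eqn{F \sim
#' \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha + \beta S))}, with S
#' one predictor difference within the pair (tarsus length, median solo
#' airspeed, or body mass: one fit per predictor). Complete separation
#' is flagged; the normal priors keep the posterior proper (wide) in
#' that case.
#'
#' @param records data.frame with `front` (0/1) and the predictor
#'   column.
#' @param predictor predictor column name.
#' @param prior_sd normal prior SD on both coefficients (default 2.5).
#' @param chains,warmup,iter,seed MCMC budget and seed.
#' @return a `posterior_summary` with parameters `alpha`, `beta`.
#' @export
fit_leadership_model <- function(records, predictor, prior_sd = 2.5,
                                 chains = 4, warmup = 2000, iter = 2000,
                                 seed = 1L) {
  f <- records$front
  s <- records[[predictor]]
  if (any(!f %in% c(0, 1))) stop("front must be 0/1")
  notes <- character(0)
  if (length(unique(f)) == 2) {
    hi <- range(s[f == 1]); lo <- range(s[f == 0])
    if (lo[2] < hi[1] || hi[2] < lo[1]) {
      notes <- "complete separation: posterior driven by the prior scale"
    }
  }
  init <- c(alpha = 0, beta = 0)
  log_post <- function(par) {
    p <- stats::plogis(par[1] + par[2] * s)
    sum(stats::dbinom(f, 1, p, log = TRUE)) +
      stats::dnorm(par[1], 0, prior_sd, log = TRUE) +
      stats::dnorm(par[2], 0, prior_sd, log = TRUE)
  }
  fit <- amwg_sample(log_post, init, n_chains = chains, warmup = warmup,
                     iter = iter, seed = seed)
  new_posterior(fit$draws, fit$accept,
                paste0("leadership_model[", predictor, "]"), notes)
}
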