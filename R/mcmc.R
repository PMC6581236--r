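# Gradient-free MCMC backend: adaptive Metropolis-within-Gibbs with
# Roberts-Rosenthal batch adaptation of per-parameter proposal scales
# during warm-up (target acceptance 0.44), plus the split-chain
# Gelman-Rubin potential scale reduction factor.

#' Split-chain Gelman-Rubin statistic (R-hat)
#'
#' Each chain is split in half; R-hat compares between- and within-chain
#' variance of the resulting 2m half-chains. Values near 1 indicate the
#' chains sample the same distribution; a common convergence criterion
#' is R-hat <= 1.1 on every parameter.
#'
#' @param draws a matrix (iterations x chains) for one parameter, or a
#'   list of equal-length numeric vectors.
#' @return the potential scale reduction factor (>= 1 up to numerical
#'   tolerance).
#' @export
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("R-hat needs at least 2 chains")
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (!is.finite(w) || w <= 0) {
    return(if (stats::var(means) <= .Machine$double.eps) 1 else Inf)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# jittered chain inits
jitter_init <- function(init, chain_seed, rel = 0.1) {
  set.seed(chain_seed)
  init + stats::rnorm(length(init), 0, rel * (abs(init) + 0.5))
}

# adaptive Metropolis-within-Gibbs. log_post maps a parameter vector to
# the (unnormalised) log posterior; bounded parameters must already be
# transformed to the real line by the caller.
amwg_sample <- function(log_post, init, n_chains = 4, warmup = 2000,
                        iter = 2000, seed = 1L, scale_init = 0.2,
                        batch = 50) {
  p <- length(init)
  pn <- names(init)
  draws <- array(NA_real_, dim = c(iter, p, n_chains),
                 dimnames = list(NULL, pn, NULL))
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    chain_seed <- (as.integer(seed) + ch * 1009L) %% .Machine$integer.max
    cur <- jitter_init(init, chain_seed)
    lp <- log_post(cur)
    tries <- 0L
    while (!is.finite(lp) && tries < 50L) {
      cur <- jitter_init(init, chain_seed + tries + 1L, rel = 0.02)
      lp <- log_post(cur)
      tries <- tries + 1L
    }
    if (!is.finite(lp)) stop("could not find a finite starting point")
    ls <- rep(log(scale_init), p)
    acc_batch <- numeric(p)
    n_acc <- 0L
    total <- warmup + iter
    for (t in seq_len(total)) {
      for (j in seq_len(p)) {
        prop <- cur
        prop[j] <- cur[j] + exp(ls[j]) * stats::rnorm(1)
        lp_new <- log_post(prop)
        if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
          cur <- prop
          lp <- lp_new
          acc_batch[j] <- acc_batch[j] + 1
          if (t > warmup) n_acc <- n_acc + 1L
        }
      }
      if (t <= warmup && t %% batch == 0) {
        delta <- min(0.25, 1 / sqrt(t / batch))
        rate <- acc_batch / batch
        ls <- ls + ifelse(rate > 0.44, delta, -delta)
        acc_batch[] <- 0
      }
      if (t > warmup) draws[t - warmup, , ch] <- cur
    }
    accept[ch] <- n_acc / (iter * p)
  }
  list(draws = draws, accept = accept)
}

# posterior summary table from a draws array [iter, p, chains]
summarise_draws <- function(draws) {
  p <- dim(draws)[2]
  pn <- dimnames(draws)[[2]]
  out <- data.frame(parameter = pn, mean = NA_real_, sd = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_, rhat = NA_real_)
  for (j in seq_len(p)) {
    x <- draws[, j, ]
    out$mean[j] <- mean(x)
    out$sd[j] <- stats::sd(x)
    qs <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    out$q2.5[j] <- qs[1]
    out$q97.5[j] <- qs[2]
    out$rhat[j] <- rhat(as.matrix(x))
  }
  out
}

new_posterior <- function(draws, accept, model, notes = character(0),
                          rhat_limit = 1.1) {
  summ <- summarise_draws(draws)
  converged <- all(is.finite(summ$rhat)) && max(summ$rhat) <= rhat_limit
  if (!converged) {
    warning("non-convergence: max split R-hat = ",
            format(max(summ$rhat), digits = 4), " > ", rhat_limit)
  }
  structure(list(draws = draws, summary = summ, accept = accept,
                 model = model, converged = converged, notes = notes),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$model, "): ",
      dim(x$draws)[3], " chains x ", dim(x$draws)[1], " draws; ",
      if (x$converged) "converged" else "NOT CONVERGED", "\n", sep = "")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  df <- x$summary
  df[, -1] <- lapply(df[, -1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract draws of one parameter across chains
#'
#' @param posterior a `posterior_summary`.
#' @param parameter parameter name.
#' @return numeric vector of pooled draws.
#' @export
posterior_draws <- function(posterior, parameter) {
  j <- match(parameter, dimnames(posterior$draws)[[2]])
  if (is.na(j)) stop("unknown parameter: ", parameter)
  as.numeric(posterior$draws[, j, ])
}

#' Posterior effects relative to a solo baseline, in percent
#'
#' Divides the draws of an effect parameter by a positive baseline and
#' multiplies by 100, transforming the mean and the equal-tailed 95%
#' interval endpoints alike.
#'
#' @param posterior a `posterior_summary`, or a numeric vector of
#'   effect draws, or a single effect value.
#' @param solo_baseline baseline value (> 0), in the response units.
#' @param parameter parameter name when `posterior` is a
#'   `posterior_summary` (default `"delta0"`).
#' @return data.frame with `percent_mean`, `percent_q2.5`,
#'   `percent_q97.5`.
#' @export
relative_effects <- function(posterior, solo_baseline,
                             parameter = "delta0") {
  if (solo_baseline == 0) stop("solo_baseline must be non-zero")
  x <- if (inherits(posterior, "posterior_summary")) {
    posterior_draws(posterior, parameter)
  } else as.numeric(posterior)
  pct <- x / solo_baseline * 100
  if (length(pct) == 1) {
    return(data.frame(percent_mean = pct, percent_q2.5 = pct,
                      percent_q97.5 = pct))
  }
  qs <- stats::quantile(pct, c(0.025, 0.975), names = FALSE)
  data.frame(percent_mean = mean(pct), percent_q2.5 = qs[1],
             percent_q97.5 = qs[2])
}
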