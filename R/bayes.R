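#' Standardize growth rates
#'
#' Centers and scales by the sample mean and SD (n - 1 denominator). The
#' Bayesian one-way model is fitted on this scale, where the grand mean is 0
#' and the genotype effects sum to zero.
#'
#' @param y numeric vector with at least two distinct values.
#' @return list with `z`, `mean`, `sd`.
#' @export
standardize <- function(y) {
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2) stop("cannot standardize constant data (sd = 0)")
  m <- mean(y); s <- stats::sd(y)
  list(z = (y - m) / s, mean = m, sd = s)
}

#' Precision draws under the mean/SD Gamma parameterization
#'
#' Per-genotype precisions are modelled as tau ~ Gamma(s, r) with
#' s = m^2/d^2 and r = m/d^2, so that the prior mean of tau is `m` and its
#' prior SD is `d`.
#'
#' @param n number of draws.
#' @param m prior mean of the precision (> 0).
#' @param d prior SD of the precision (> 0).
#' @return numeric vector of `n` Gamma draws.
#' @export
rprecision <- function(n, m, d) {
  stopifnot(m > 0, d > 0)
  stats::rgamma(n, shape = m^2 / d^2, rate = m / d^2)
}

#' Hierarchical one-way model specification
#'
#' Hyperconstants of the heterogeneous-variance Bayesian ANOVA: genotype
#' effects beta_j ~ Normal(0, 1/sigma_beta^2) with a folded-t(nu_beta,
#' A_beta) prior on sigma_beta; per-genotype precisions tau_j ~
#' Gamma(m^2/d^2, m/d^2) with Gamma priors on the precision mean `m` and SD
#' `d`. Defaults are weakly informative on the standardized data scale:
#' folded-t with 2 df and scale 1; Gamma hyperpriors with prior mode 1 and
#' prior SD 10.
#'
#' @param nu_beta folded-t degrees of freedom for sigma_beta.
#' @param A_beta folded-t scale for sigma_beta.
#' @param s_m,r_m Gamma shape/rate for m.
#' @param s_d,r_d Gamma shape/rate for d.
#' @param beta0_prec prior precision of the (nuisance) intercept.
#' @return list of class `hier_spec`.
#' @export
hier_spec <- function(nu_beta = 2, A_beta = 1,
                      s_m = NULL, r_m = NULL, s_d = NULL, r_d = NULL,
                      beta0_prec = 1e-6) {
  # mode 1, SD 10: mode = (s-1)/r = 1 and sqrt(s)/r = 10 give
  # 100 r^2 - r - 1 = 0
  r_def <- (1 + sqrt(401)) / 200
  if (is.null(r_m)) r_m <- r_def
  if (is.null(s_m)) s_m <- 1 + r_m
  if (is.null(r_d)) r_d <- r_def
  if (is.null(s_d)) s_d <- 1 + r_d
  stopifnot(nu_beta > 0, A_beta > 0, s_m > 0, r_m > 0, s_d > 0, r_d > 0)
  structure(list(nu_beta = nu_beta, A_beta = A_beta,
                 s_m = s_m, r_m = r_m, s_d = s_d, r_d = r_d,
                 beta0_prec = beta0_prec),
            class = "hier_spec")
}

#' MCMC configuration
#'
#' @param n_chains number of chains (default 5).
#' @param burn_in burn-in iterations per chain (default 10000).
#' @param n_saved saved draws per chain (default 2000).
#' @param thin thinning interval between saved draws (default 5).
#' @param seed master seed.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5, burn_in = 10000, n_saved = 2000,
                        thin = 5, seed = 1L) {
  stopifnot(n_chains >= 1, burn_in >= 0, n_saved >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_saved = as.integer(n_saved),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

# log folded-t density (up to a constant) for a scale parameter s > 0
log_folded_t <- function(s, nu, A) {
  if (s <= 0) return(-Inf)
  -((nu + 1) / 2) * log1p((s / A)^2 / nu)
}

# one chain of the Metropolis-within-Gibbs sampler; returns a numeric
# matrix of saved draws (already swept to sum(beta) = 0)
run_chain <- function(S, SS, nvec, spec, burn_in, n_saved, thin, seed) {
  J <- length(nvec)
  set.seed(seed)
  # initial values from the data summaries
  gmean <- S / nvec
  beta0 <- 0
  beta <- gmean - mean(gmean)
  gvar <- pmax((SS - S^2 / nvec) / pmax(nvec - 1, 1), 1e-3)
  tau <- 1 / gvar
  sigma_beta <- max(stats::sd(beta), 0.1)
  m <- mean(tau); d <- max(stats::sd(tau), 0.5 * m)

  ls_sig <- log(0.5); ls_m <- log(0.5); ls_d <- log(0.5); ls_md <- log(0.5)
  acc <- c(sig = 0, m = 0, d = 0, md = 0); tries <- 0

  n_iter <- burn_in + n_saved * thin
  out <- matrix(NA_real_, n_saved, 1 + 2 * J + 3)
  save_row <- 0L

  log_tau_cond <- function(mm, dd, tau) {
    sG <- mm^2 / dd^2; rG <- mm / dd^2
    sum(stats::dgamma(tau, shape = sG, rate = rG, log = TRUE))
  }

  for (it in seq_len(n_iter)) {
    # intercept and effects: conjugate normal updates
    prec0 <- spec$beta0_prec + sum(nvec * tau)
    mean0 <- sum(tau * (S - nvec * beta)) / prec0
    beta0 <- stats::rnorm(1, mean0, 1 / sqrt(prec0))
    tau_beta <- 1 / sigma_beta^2
    precj <- tau_beta + nvec * tau
    meanj <- tau * (S - nvec * beta0) / precj
    beta <- stats::rnorm(J, meanj, 1 / sqrt(precj))

    # per-genotype precisions: conjugate gamma update
    ssr <- SS - 2 * (beta0 + beta) * S + nvec * (beta0 + beta)^2
    sG <- m^2 / d^2; rG <- m / d^2
    tau <- stats::rgamma(J, shape = sG + nvec / 2, rate = rG + ssr / 2)

    # sigma_beta: random-walk Metropolis on the log scale
    prop <- sigma_beta * exp(stats::rnorm(1, 0, exp(ls_sig)))
    log_r <- sum(stats::dnorm(beta, 0, prop, log = TRUE)) -
      sum(stats::dnorm(beta, 0, sigma_beta, log = TRUE)) +
      log_folded_t(prop, spec$nu_beta, spec$A_beta) -
      log_folded_t(sigma_beta, spec$nu_beta, spec$A_beta) +
      log(prop) - log(sigma_beta)           # log-scale proposal Jacobian
    if (log(stats::runif(1)) < log_r) { sigma_beta <- prop; acc["sig"] <- acc["sig"] + 1 }

    # m and d: random-walk Metropolis on the log scale. They are strongly
    # correlated a posteriori, so single-site moves are repeated and
    # complemented by a joint move scaling both by a common factor.
    for (rep_md in 1:3) {
      prop <- m * exp(stats::rnorm(1, 0, exp(ls_m)))
      log_r <- log_tau_cond(prop, d, tau) - log_tau_cond(m, d, tau) +
        stats::dgamma(prop, spec$s_m, rate = spec$r_m, log = TRUE) -
        stats::dgamma(m, spec$s_m, rate = spec$r_m, log = TRUE) +
        log(prop) - log(m)
      if (is.finite(log_r) && log(stats::runif(1)) < log_r) { m <- prop; acc["m"] <- acc["m"] + 1 }

      prop <- d * exp(stats::rnorm(1, 0, exp(ls_d)))
      log_r <- log_tau_cond(m, prop, tau) - log_tau_cond(m, d, tau) +
        stats::dgamma(prop, spec$s_d, rate = spec$r_d, log = TRUE) -
        stats::dgamma(d, spec$s_d, rate = spec$r_d, log = TRUE) +
        log(prop) - log(d)
      if (is.finite(log_r) && log(stats::runif(1)) < log_r) { d <- prop; acc["d"] <- acc["d"] + 1 }

      fac <- exp(stats::rnorm(1, 0, exp(ls_md)))
      pm <- m * fac; pd <- d * fac
      log_r <- log_tau_cond(pm, pd, tau) - log_tau_cond(m, d, tau) +
        stats::dgamma(pm, spec$s_m, rate = spec$r_m, log = TRUE) -
        stats::dgamma(m, spec$s_m, rate = spec$r_m, log = TRUE) +
        stats::dgamma(pd, spec$s_d, rate = spec$r_d, log = TRUE) -
        stats::dgamma(d, spec$s_d, rate = spec$r_d, log = TRUE) +
        2 * log(fac)
      if (is.finite(log_r) && log(stats::runif(1)) < log_r) {
        m <- pm; d <- pd; acc["md"] <- acc["md"] + 1
      }
    }

    tries <- tries + 3

    # adapt proposal scales during burn-in only (frozen afterwards)
    if (it <= burn_in && it %% 50 == 0) {
      sig_tries <- tries / 3  # sigma_beta is updated once per iteration
      rate <- c(acc["sig"] / sig_tries, acc[c("m", "d", "md")] / tries)
      ls_sig <- ls_sig + 0.5 * (rate["sig"] - 0.44)
      ls_m <- ls_m + 0.5 * (rate["m"] - 0.44)
      ls_d <- ls_d + 0.5 * (rate["d"] - 0.44)
      ls_md <- ls_md + 0.5 * (rate["md"] - 0.44)
      acc[] <- 0; tries <- 0
    }

    # identifiability sweep: fold mean(beta) into the intercept
    mb <- mean(beta)
    beta0 <- beta0 + mb
    beta <- beta - mb

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      save_row <- save_row + 1L
      out[save_row, ] <- c(beta0, beta, tau, sigma_beta, m, d)
    }
  }
  out
}

#' Sample the posterior of the hierarchical one-way model
#'
#' Fits the heterogeneous-variance Bayesian ANOVA to the growth rates of one
#' environmental cell (one parameter at one setting): observations are
#' normal around a genotype mean with genotype-specific precision; genotype
#' effects shrink toward zero under a common scale with a folded-t prior;
#' precisions share a Gamma prior whose mean and SD are themselves
#' estimated. Sampling is Metropolis-within-Gibbs (conjugate updates for
#' effects and precisions; adaptive-then-frozen log-scale random walks for
#' the three hyperparameters), with a sum-to-zero sweep of the effects after
#' every iteration. Identical seeds give identical draws.
#'
#' @param table growth-rate table (or any data.frame with `genotype` and
#'   `rate`); optionally filtered by `env_param` and `setting`.
#' @param env_param,setting optional filters selecting one environment cell.
#' @param spec a [hier_spec()].
#' @param cfg an [mcmc_config()].
#' @return list of class `posterior_draws`: `draws` (data.frame with
#'   `chain`, `iter`, `beta0`, `beta.<genotype>`, `tau.<genotype>`,
#'   `sigma_beta`, `m`, `d`, on the standardized scale), `genotypes`,
#'   `scale` (list mean/sd of the data), `cfg`, `spec`.
#' @export
sample_posterior <- function(table, env_param = NULL, setting = NULL,
                             spec = hier_spec(), cfg = mcmc_config()) {
  d <- as.data.frame(table)
  if (!is.null(env_param)) d <- d[d$env_param == env_param, , drop = FALSE]
  if (!is.null(setting)) d <- d[d$setting == setting, , drop = FALSE]
  d <- d[!is.na(d$rate), , drop = FALSE]
  gens <- sort(unique(d$genotype))
  if (length(gens) < 2) stop("need at least 2 genotypes in the cell")
  nvec <- table(factor(d$genotype, levels = gens))
  if (any(nvec < 2)) stop("every genotype needs >= 2 observations; short: ",
                          paste(gens[nvec < 2], collapse = ", "))
  std <- standardize(d$rate)
  z <- std$z
  g <- factor(d$genotype, levels = gens)
  S <- as.numeric(tapply(z, g, sum))
  SS <- as.numeric(tapply(z, g, function(v) sum(v^2)))
  nvec <- as.numeric(nvec)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  chain_seeds <- sample.int(2147483646L, cfg$n_chains)
  chains <- lapply(seq_len(cfg$n_chains), function(ci) {
    mat <- run_chain(S, SS, nvec, spec, cfg$burn_in, cfg$n_saved, cfg$thin,
                     chain_seeds[ci])
    cbind(chain = ci, iter = seq_len(nrow(mat)), mat)
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  all <- as.data.frame(do.call(rbind, chains))
  names(all) <- c("chain", "iter", "beta0",
                  paste0("beta.", gens), paste0("tau.", gens),
                  "sigma_beta", "m", "d")
  structure(list(draws = all, genotypes = gens,
                 scale = list(mean = std$mean, sd = std$sd),
                 cfg = cfg, spec = spec),
            class = "posterior_draws")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws; on ties the lowest-start window is returned.
#'
#' @param samples numeric draws (>= 100).
#' @param mass probability mass in (0, 1), default 0.95.
#' @return numeric length-2 vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 100) stop("need at least 100 draws for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1])
}

#' Mutant-minus-control posterior contrast
#'
#' Per-draw difference of the genotype effects, rescaled to mm/hr by the
#' data SD. A strain growing slower than the control has a negative
#' difference. The contrast is significant when the 95% HPD interval
#' excludes zero.
#'
#' @param draws a `posterior_draws` object.
#' @param mutant,control genotype labels present in the draws.
#' @param mass HPD mass (default 0.95).
#' @return list of class `contrast_result`: `mutant`, `control`,
#'   `mean_diff`, `hpd_low`, `hpd_high`, `significant`.
#' @export
compute_contrast <- function(draws, mutant, control, mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  for (lab in c(mutant, control))
    if (!lab %in% draws$genotypes)
      stop("genotype '", lab, "' not in the posterior draws")
  dm <- draws$draws[[paste0("beta.", mutant)]]
  dc <- draws$draws[[paste0("beta.", control)]]
  diff <- draws$scale$sd * (dm - dc)
  hpd <- hpd_interval(diff, mass)
  structure(list(mutant = mutant, control = control,
                 mean_diff = mean(diff),
                 hpd_low = hpd[1], hpd_high = hpd[2],
                 significant = hpd[1] > 0 || hpd[2] < 0),
            class = "contrast_result")
}

#' All mutant-vs-control contrasts of a fit
#'
#' @param draws a `posterior_draws`.
#' @param control control genotype label.
#' @param mass HPD mass.
#' @return data.frame with one row per mutant.
#' @export
contrast_table <- function(draws, control = "4200", mass = 0.95) {
  mutants <- setdiff(draws$genotypes, control)
  rows <- lapply(mutants, function(m) {
    cr <- compute_contrast(draws, m, control, mass)
    data.frame(mutant = m, control = control, mean_diff = cr$mean_diff,
               hpd_low = cr$hpd_low, hpd_high = cr$hpd_high,
               significant = cr$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- convergence diagnostics ----------------------------------------------

rank_normalize <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

# split-chain potential scale reduction on rank-normalized draws
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  z <- matrix(rank_normalize(as.vector(sub)), nrow = half)
  W <- mean(apply(z, 2, stats::var))
  B <- half * stats::var(colMeans(z))
  sqrt(((half - 1) / half * W + B / half) / W)
}

# multi-chain effective sample size (Geyer initial monotone sequence)
multi_ess <- function(mat) {
  n <- nrow(mat); nc <- ncol(mat)
  if (n < 4) return(NA_real_)
  chain_var <- apply(mat, 2, stats::var)
  W <- mean(chain_var)
  B_over_n <- if (nc > 1) stats::var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus <= 0) return(n * nc)
  max_lag <- min(n - 2, 1000)
  acov <- sapply(seq_len(nc), function(j)
    stats::acf(mat[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive and non-increasing
  npair <- floor(length(rho) / 2)
  psum <- rho[seq(1, 2 * npair, by = 2)] + rho[seq(2, 2 * npair, by = 2)]
  pos <- which(psum <= 0)
  if (length(pos)) psum <- psum[seq_len(pos[1] - 1)]
  if (length(psum)) psum <- cummin(psum)
  tau <- 1 + 2 * sum(psum)
  max(1, n * nc / max(tau, 1e-8))
}

#' MCMC convergence diagnostics
#'
#' Rank-normalized split potential scale reduction (R-hat) and effective
#' sample size per parameter. The fit passes when every R-hat is below
#' `rhat_max` and every ESS exceeds `ess_min`.
#'
#' @param draws a `posterior_draws` with at least 2 chains.
#' @param rhat_max R-hat threshold (default 1.01).
#' @param ess_min ESS threshold (default 400).
#' @return list with `rhat` (named), `ess` (named), `pass` (logical).
#' @export
convergence_diagnostics <- function(draws, rhat_max = 1.01, ess_min = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  dd <- draws$draws
  chains <- sort(unique(dd$chain))
  if (length(chains) < 2)
    stop("R-hat needs at least 2 chains")
  pars <- setdiff(names(dd), c("chain", "iter"))
  per_par <- function(p) {
    mat <- sapply(chains, function(ci) dd[[p]][dd$chain == ci])
    c(rhat = split_rhat(mat), ess = multi_ess(mat))
  }
  res <- vapply(pars, per_par, numeric(2))
  rhat <- stats::setNames(res["rhat", ], pars)
  ess <- stats::setNames(res["ess", ], pars)
  # the swept intercept can be numerically constant; drop NaN rhat
  ok <- is.finite(rhat)
  list(rhat = rhat, ess = ess,
       pass = all(rhat[ok] < rhat_max) && all(ess[ok] > ess_min))
}
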