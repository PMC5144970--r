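# shared fixture builders (everything is generated in code at test time)

# minimal single-genotype table on a given grid
one_genotype_table <- function(rates_by_setting, n_rep = 5, sd = 0,
                               env_param = "temperature", seed = NULL,
                               genotype = "g1") {
  if (!is.null(seed)) set.seed(seed)
  grid <- as.numeric(names(rates_by_setting))
  n <- length(grid) * n_rep
  data.frame(
    genotype = genotype, mechanism = "control", env_param = env_param,
    setting = rep(grid, each = n_rep), replicate = rep(seq_len(n_rep),
                                                       length(grid)),
    rate = pmax(0, rep(unname(rates_by_setting), each = n_rep) +
                  stats::rnorm(n, 0, sd)),
    stringsAsFactors = FALSE)
}

# two-genotype factorial cell data for pairwise tests
two_genotype_table <- function(mu_ctrl, mu_mut, n_rep = 5, sd = 0.2,
                               env_param = "temperature", seed = 1) {
  set.seed(seed)
  grid <- as.numeric(names(mu_ctrl))
  rbind(
    data.frame(genotype = "4200", mechanism = "control",
               env_param = env_param,
               setting = rep(grid, each = n_rep),
               replicate = rep(seq_len(n_rep), length(grid)),
               rate = rep(unname(mu_ctrl), each = n_rep) +
                 rnorm(length(grid) * n_rep, 0, sd)),
    data.frame(genotype = "mut", mechanism = "other",
               env_param = env_param,
               setting = rep(grid, each = n_rep),
               replicate = rep(seq_len(n_rep), length(grid)),
               rate = rep(unname(mu_mut), each = n_rep) +
                 rnorm(length(grid) * n_rep, 0, sd)))
}

# one-environment-cell table for the Bayesian model
bayes_cell_table <- function(means, sds, n_per = 12, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(means), function(i)
    data.frame(genotype = names(means)[i], env_param = "salt", setting = 0.8,
               rate = rnorm(n_per, means[i], sds[i]),
               stringsAsFactors = FALSE)))
}

# definition-based Holm oracle: step-down over sorted p-values
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# brute-force HPD oracle: scan every window of ceil(mass*n) sorted draws
hpd_oracle <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  best <- c(s[1], s[k]); bw <- s[k] - s[1]
  for (i in 2:(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < bw - 1e-15) { bw <- w; best <- c(s[i], s[i + k - 1]) }
  }
  best
}

# eq2-style synthetic data with a known genotype variance component
eq2_sim <- function(n_geno = 12, n_set = 6, n_rep = 3, sigma_g = 0.2,
                    sigma_e = 0.2, seed = 1) {
  set.seed(seed)
  g_eff <- rnorm(n_geno, 0, sigma_g)
  set_eff <- seq(-0.5, 0.5, length.out = n_set)
  d <- expand.grid(genotype = paste0("g", seq_len(n_geno)),
                   setting = seq_len(n_set), replicate = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  d$mechanism <- rep(c("a", "b"), length.out = n_geno)[
    match(d$genotype, paste0("g", seq_len(n_geno)))]
  d$env_param <- "temperature"
  d$rate <- 3 + g_eff[match(d$genotype, paste0("g", seq_len(n_geno)))] +
    set_eff[d$setting] + rnorm(nrow(d), 0, sigma_e)
  d
}
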