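#' Holm (step-down Bonferroni) p-value adjustment
#'
#' Sorts ascending, multiplies the i-th smallest by (m - i + 1), enforces
#' monotonicity with a running maximum, caps at 1, and returns the values in
#' the original order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
holm_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0 | pvals > 1))
    stop("pvals must be numeric in [0, 1] with no NAs")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- data preparation -------------------------------------------------------

# Factors with sum-to-zero contrasts (required for Type III hypotheses).
# E is the setting's rank within its environmental parameter, so that the
# same six-level factor can be crossed with the parameter factor.
prepare_anova_data <- function(table, env_param = NULL) {
  d <- as.data.frame(table)
  d <- d[!is.na(d$rate), , drop = FALSE]
  if (!is.null(env_param)) {
    d <- d[d$env_param == env_param, , drop = FALSE]
    if (nrow(d) == 0L) stop("no data for env_param '", env_param, "'")
  }
  d$E <- NA_integer_
  for (p in unique(d$env_param)) {
    i <- which(d$env_param == p)
    grid <- sort(unique(d$setting[i]))
    d$E[i] <- match(d$setting[i], grid)
  }
  d$E <- factor(d$E)
  d$M <- factor(d$mechanism)
  d$S <- factor(d$env_param)
  d$G <- factor(d$genotype)
  for (f in c("E", "M", "S", "G"))
    if (nlevels(d[[f]]) > 1)
      stats::contrasts(d[[f]]) <- stats::contr.sum(nlevels(d[[f]]))
  d
}

#' Fit the reaction-norm mixed models
#'
#' Two REML mixed models for growth rate. The overall model (`"eq1"`) has
#' fixed effects for epigenetic mechanism (M), environmental parameter (S),
#' setting nested within parameter (E within S), and the M x S and
#' M x E-within-S interactions, with random intercepts for genotype (G),
#' G x S and G x E-within-S. The per-parameter model (`"eq2"`) keeps M, E
#' and M x E fixed with G and G x E random, on one environmental parameter's
#' data. Settings are unordered factors (the norms are nonlinear) and all
#' factors use sum-to-zero contrasts so Type III tests are meaningful.
#'
#' @param table growth-rate table (long format); rows with missing rate are
#'   dropped (complete-case analysis).
#' @param model `"eq1"` (all data) or `"eq2"` (one parameter).
#' @param env_param required for `"eq2"`: which parameter to analyse.
#' @param extra_fixed optional name of a column to add as a fixed covariate
#'   (e.g. growth-chamber identity).
#' @return A list of class `pn_mixed_fit` wrapping the `lmerMod` (or `lm`
#'   when no random term is estimable) plus fitting metadata.
#' @export
fit_mixed_model <- function(table, model = c("eq1", "eq2"), env_param = NULL,
                            extra_fixed = NULL) {
  model <- match.arg(model)
  if (model == "eq2" && is.null(env_param))
    stop("model 'eq2' needs env_param")
  d <- prepare_anova_data(table, if (model == "eq2") env_param else NULL)
  fixed <- if (model == "eq1")
    "M + S + S:E + M:S + M:S:E"
  else
    "M + E + M:E"
  if (!is.null(extra_fixed)) {
    if (!extra_fixed %in% names(d)) stop("no column '", extra_fixed, "'")
    if (!is.factor(d[[extra_fixed]])) d[[extra_fixed]] <- factor(d[[extra_fixed]])
    if (nlevels(d[[extra_fixed]]) > 1)
      stats::contrasts(d[[extra_fixed]]) <- stats::contr.sum(nlevels(d[[extra_fixed]]))
    fixed <- paste(extra_fixed, "+", fixed)
  }
  random <- if (model == "eq1")
    c("(1 | G)", "(1 | G:S)", "(1 | G:S:E)")
  else
    c("(1 | G)", "(1 | G:E)")
  fit_mixed_formula(fixed, random, d, model = model, env_param = env_param)
}

# core fitter: fixed part (string), random bar terms (character vector)
fit_mixed_formula <- function(fixed, random, data, model = NA_character_,
                              env_param = NULL) {
  form <- stats::as.formula(
    paste("rate ~", paste(c(fixed, random), collapse = " + ")))
  if (length(random) == 0L) {
    fit <- stats::lm(stats::as.formula(paste("rate ~", fixed)), data = data)
    obj <- list(fit = fit, kind = "lm", fixed = fixed, random = character(0),
                data = data, model = model, env_param = env_param)
    class(obj) <- "pn_mixed_fit"
    return(obj)
  }
  # tight optimizer tolerances: Satterthwaite df inherit the precision of
  # the variance-parameter estimates
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", calc.derivs = FALSE,
                      optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14)))
  obj <- list(fit = fit, kind = "lmer", fixed = fixed, random = random,
              data = data, model = model, env_param = env_param,
              theta = polish_theta(fit))
  class(obj) <- "pn_mixed_fit"
  obj
}

# Newton refinement of the profiled REML optimum: generic optimizers stop
# within ~1e-8 of the solution, which is visible in the Satterthwaite df.
polish_theta <- function(fit, steps = 3) {
  th <- lme4::getME(fit, "theta")
  devfun <- tryCatch(stats::update(fit, devFunOnly = TRUE),
                     error = function(e) NULL)
  if (is.null(devfun)) return(th)
  fdg <- function(f, x, h) {
    k <- length(x)
    vapply(seq_len(k), function(i) {
      e <- replace(numeric(k), i, 1)
      d1 <- (f(x + e * h[i] / 2) - f(x - e * h[i] / 2)) / h[i]
      d2 <- (f(x + e * h[i]) - f(x - e * h[i])) / (2 * h[i])
      (4 * d1 - d2) / 3
    }, 0)
  }
  out <- tryCatch({
    cur <- th
    for (it in seq_len(steps)) {
      h <- pmax(1e-3, 1e-3 * abs(cur))
      g <- fdg(devfun, cur, h)
      H <- fd_hessian(devfun, cur, h)
      step <- solve(H, g)
      if (any(!is.finite(step)) || max(abs(step)) > 0.1) break
      cur <- cur - step
    }
    if (is.finite(devfun(cur)) && devfun(cur) <= devfun(th) + 1e-8 &&
        all(cur >= 0)) cur else th
  }, error = function(e) th)
  out
}

#' @export
print.pn_mixed_fit <- function(x, ...) {
  cat("Mixed model fit (", x$kind, ")\n", sep = "")
  cat("fixed:  rate ~", x$fixed, "\n")
  if (length(x$random)) cat("random:", paste(x$random, collapse = " + "), "\n")
  invisible(x)
}

# ---- REML criterion and vcov(beta) as functions of (theta, sigma) ----------
# Rebuilt from the model matrices so that Satterthwaite gradients and the
# Hessian of the criterion can be taken by central finite differences.

reml_env <- function(fit) {
  X <- lme4::getME(fit, "X")
  list(X = X,
       y = lme4::getME(fit, "y"),
       Zt = lme4::getME(fit, "Zt"),
       Lambdat = lme4::getME(fit, "Lambdat"),
       Lind = lme4::getME(fit, "Lind"),
       n = nrow(X), p = ncol(X))
}

# -2 * restricted log-likelihood at (theta, sigma), including constants,
# matching lme4's REML criterion at the optimum. Also returns beta and
# vcov(beta) = sigma^2 (X' Sigma^-1 X)^-1 with Sigma = I + Z Lambda Lambda' Z'.
reml_eval <- function(env, theta, sigma) {
  Lambdat <- env$Lambdat
  Lambdat@x <- theta[env$Lind]
  LZ <- Lambdat %*% env$Zt
  Sigma <- Matrix::Diagonal(env$n) + Matrix::crossprod(LZ)
  SigInvX <- as.matrix(Matrix::solve(Sigma, env$X))
  SigInvy <- as.numeric(Matrix::solve(Sigma, env$y))
  XtSiX <- crossprod(env$X, SigInvX)
  beta <- solve(XtSiX, crossprod(SigInvX, env$y))
  r <- env$y - env$X %*% beta
  quad <- sum(r * as.numeric(Matrix::solve(Sigma, r)))
  ld_Sigma <- as.numeric(Matrix::determinant(Sigma, logarithm = TRUE)$modulus)
  ld_XtSiX <- as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus)
  crit <- (env$n - env$p) * log(2 * pi * sigma^2) + ld_Sigma + ld_XtSiX +
    quad / sigma^2
  list(crit = crit, beta = drop(beta), vcov = sigma^2 * solve(XtSiX),
       quad = quad)
}

varpar_hat <- function(fit) c(lme4::getME(fit, "theta"), sigma = stats::sigma(fit))

# Hessian of the REML criterion by central finite differences with one
# Richardson extrapolation step (truncation error O(h^4))
fd_hessian_raw <- function(f, x, h) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

fd_hessian <- function(f, x, h = pmax(1e-2, 1e-2 * abs(x))) {
  (4 * fd_hessian_raw(f, x, h / 2) - fd_hessian_raw(f, x, h)) / 3
}

# ---- Type III F-tests with Satterthwaite denominator df --------------------

#' Type III F-tests for the fixed effects of a mixed model
#'
#' For each fixed term, the Wald F statistic from the sum-to-zero contrast
#' selecting that term's coefficients (the Type III hypothesis). For mixed
#' fits the denominator degrees of freedom use the Satterthwaite
#' approximation: the contrast covariance is eigendecomposed into
#' independent 1-df contrasts, each contrast's variance is differentiated
#' with respect to the variance parameters (theta, sigma) by central finite
#' differences, the parameter covariance comes from the inverse Hessian of
#' the REML criterion, and the per-contrast df are pooled. For `lm` fits the
#' denominator df are exact (n - p).
#'
#' @param handle a `pn_mixed_fit` from [fit_mixed_model()].
#' @return data.frame (class `anova_result`) with one row per fixed term:
#'   `term`, `F_value`, `df1`, `df2`, `p_value`.
#' @export
type3_tests <- function(handle) {
  stopifnot(inherits(handle, "pn_mixed_fit"))
  fit <- handle$fit
  if (handle$kind == "lm") return(lm_type3(fit))

  env <- reml_env(fit)
  theta <- if (!is.null(handle$theta)) handle$theta else lme4::getME(fit, "theta")
  # profiled REML sigma at the (polished) theta
  quad <- reml_eval(env, theta, 1)$quad
  vp <- c(theta, sigma = sqrt(quad / (env$n - env$p)))
  ev0 <- reml_eval(env, vp[-length(vp)], vp[length(vp)])
  beta <- ev0$beta
  V <- ev0$vcov

  # d vcov(beta) / d varpar_j by Richardson-extrapolated central differences.
  # The gradient tolerates a small step (roundoff ~ eps/h); the Hessian of
  # the criterion needs a larger one (roundoff ~ eps/h^2).
  h <- pmax(3e-4, 3e-4 * abs(vp))
  hH <- pmax(6e-3, 6e-3 * abs(vp))
  k <- length(vp)
  vcov_at <- function(j, delta) {
    vpj <- vp; vpj[j] <- vp[j] + delta
    reml_eval(env, vpj[-k], vpj[k])$vcov
  }
  dV <- lapply(seq_len(k), function(j) {
    d1 <- (vcov_at(j, h[j] / 2) - vcov_at(j, -h[j] / 2)) / h[j]
    d2 <- (vcov_at(j, h[j]) - vcov_at(j, -h[j])) / (2 * h[j])
    (4 * d1 - d2) / 3
  })
  crit_fun <- function(x) reml_eval(env, x[-k], x[k])$crit
  # second Richardson level: truncation O(h^6) at still-benign roundoff
  H <- (16 * fd_hessian(crit_fun, vp, hH / 2) -
          fd_hessian(crit_fun, vp, hH)) / 15
  A <- tryCatch(2 * solve(H), error = function(e) {
    warning("singular Hessian of the REML criterion; using pseudo-inverse")
    2 * MASS_ginv(H)
  })

  X <- env$X
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(fit, fixed.only = TRUE), "term.labels")
  rows <- lapply(seq_along(labs), function(ti) {
    cols <- which(asgn == ti)
    if (!length(cols)) return(NULL)
    L <- diag(env$p)[cols, , drop = FALSE]
    satterthwaite_term(labs[ti], L, beta, V, dV, A)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# F and pooled Satterthwaite df for one (possibly multi-df) contrast L
satterthwaite_term <- function(label, L, beta, V, dV, A) {
  Phi <- L %*% V %*% t(L)
  e <- eigen(Phi, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-8
  if (!any(pos)) {
    warning("singular contrast for term '", label, "'; skipped")
    return(NULL)
  }
  if (any(!pos))
    warning("contrast for term '", label, "' is rank deficient; using rank ",
            sum(pos))
  U <- e$vectors[, pos, drop = FALSE]
  d <- e$values[pos]
  q <- length(d)
  UL <- t(U) %*% L                       # q x p, rows are 1-df contrasts
  t2 <- (as.numeric(UL %*% beta))^2 / d
  Fval <- sum(t2) / q

  k <- length(dV)
  nu <- vapply(seq_len(q), function(i) {
    li <- UL[i, ]
    g <- vapply(seq_len(k), function(j)
      as.numeric(li %*% dV[[j]] %*% li), 0)
    vv <- as.numeric(t(g) %*% A %*% g)
    if (vv <= 0) Inf else 2 * d[i]^2 / vv
  }, 0)

  Esum <- sum(ifelse(nu > 2, nu / (nu - 2), 0))
  df2 <- if (Esum > q) 2 * Esum / (Esum - q) else Inf
  data.frame(term = label, F_value = Fval, df1 = q, df2 = df2,
             p_value = stats::pf(Fval, q, df2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# Type III tests for a plain lm (exact residual df)
lm_type3 <- function(fit) {
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  df2 <- stats::df.residual(fit)
  labs <- attr(stats::terms(fit), "term.labels")
  rows <- lapply(seq_along(labs), function(ti) {
    cols <- which(asgn == ti)
    if (!length(cols)) return(NULL)
    b <- beta[cols]
    Vi <- V[cols, cols, drop = FALSE]
    q <- length(cols)
    Fval <- as.numeric(t(b) %*% solve(Vi, b)) / q
    data.frame(term = labs[ti], F_value = Fval, df1 = q, df2 = df2,
               p_value = stats::pf(Fval, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# minimal Moore-Penrose inverse (avoids a MASS dependency)
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# ---- likelihood-ratio tests for variance components ------------------------

# REML criterion of an lm on the same scale as lme4's (constants included)
lm_reml_crit <- function(fixed, data) {
  fit <- stats::lm(stats::as.formula(paste("rate ~", fixed)), data = data)
  X <- stats::model.matrix(fit)
  n <- nrow(X); p <- fit$rank
  rss <- sum(stats::residuals(fit)^2)
  qrX <- qr(X)
  ld <- 2 * sum(log(abs(diag(qr.R(qrX))[seq_len(p)])))
  (n - p) * (1 + log(2 * pi * rss / (n - p))) + ld
}

#' Likelihood-ratio chi-square test for one random term
#'
#' Refits the model without the named random term (REML, identical fixed
#' effects) and reports chi2 = criterion(reduced) - criterion(full) on 1 df
#' (one variance component removed). When the estimate sits on the boundary
#' (variance 0) the naive chi2(1) reference is conservative; the test is
#' reported as-is.
#'
#' @param handle a `pn_mixed_fit` with at least one random term.
#' @param term the random term to delete, e.g. `"G"`, `"G:E"`, or the full
#'   bar form `"(1 | G:E)"`.
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt_random_effects <- function(handle, term) {
  stopifnot(inherits(handle, "pn_mixed_fit"))
  if (handle$kind != "lmer") stop("fit has no random terms")
  bars <- handle$random
  groups <- gsub("^\\(1 \\| (.*)\\)$", "\\1", bars)
  i <- match(term, bars)
  if (is.na(i)) i <- match(term, groups)
  if (is.na(i))
    stop("'", term, "' is not a random term of this fit (have: ",
         paste(groups, collapse = ", "), ")")
  full_crit <- lme4::REMLcrit(handle$fit)
  remaining <- bars[-i]
  red_crit <- if (length(remaining)) {
    red <- fit_mixed_formula(handle$fixed, remaining, handle$data)
    lme4::REMLcrit(red$fit)
  } else {
    lm_reml_crit(handle$fixed, handle$data)
  }
  chi2 <- max(0, red_crit - full_crit)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' All-random-terms chi-square table
#'
#' @param handle a `pn_mixed_fit`.
#' @return data.frame with `term`, `chi2`, `df`, `p_value`.
#' @export
random_effects_tests <- function(handle) {
  groups <- gsub("^\\(1 \\| (.*)\\)$", "\\1", handle$random)
  rows <- lapply(groups, function(g) {
    r <- lrt_random_effects(handle, g)
    data.frame(term = g, chi2 = r$chi2, df = r$df, p_value = r$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- pairwise control-vs-mutant interaction tests --------------------------

#' Pairwise genotype-by-setting interaction tests against a control
#'
#' For each mutant, fits the two-genotype model `rate ~ genotype * setting`
#' (settings as factors, sum-to-zero contrasts) on the control-plus-mutant
#' subset of one environmental parameter and extracts the Type III F-test
#' p-value of the genotype x setting interaction (a shape change of the
#' reaction norm). P-values are then Holm-adjusted across mutants.
#'
#' @param table growth-rate table.
#' @param control control genotype label (default `"4200"`).
#' @param env_param environmental parameter to analyse.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame (class `pairwise_test_table`): `mutant`, `p_raw`,
#'   `p_holm`, `significant`.
#' @export
pairwise_control_tests <- function(table, control = "4200", env_param,
                                   alpha = 0.05) {
  d0 <- as.data.frame(table)
  d0 <- d0[d0$env_param == env_param & !is.na(d0$rate), , drop = FALSE]
  if (!control %in% d0$genotype)
    stop("control genotype '", control, "' not present in ", env_param)
  mutants <- setdiff(unique(d0$genotype), control)
  if (!length(mutants)) stop("no mutants to compare")
  rows <- lapply(mutants, function(m) {
    d <- d0[d0$genotype %in% c(control, m), , drop = FALSE]
    if (length(unique(d$setting[d$genotype == m])) < 2) {
      warning("mutant '", m, "' has <2 settings of data; skipped")
      return(NULL)
    }
    d$G <- factor(d$genotype, levels = c(control, m))
    d$E <- factor(d$setting)
    stats::contrasts(d$G) <- stats::contr.sum(2)
    stats::contrasts(d$E) <- stats::contr.sum(nlevels(d$E))
    fit <- stats::lm(rate ~ G * E, data = d)
    tab <- lm_type3(fit)
    p <- tab$p_value[tab$term == "G:E"]
    data.frame(mutant = m, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no testable mutants")
  out$p_holm <- holm_adjust(out$p_raw)
  out$significant <- out$p_holm < alpha
  rownames(out) <- NULL
  class(out) <- c("pairwise_test_table", "data.frame")
  out
}
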