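test_that("holm_adjust matches hand-worked and oracle values", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.5, 1.2)))
  expect_error(holm_adjust(c(0.5, NA)))
  # random vectors: exact agreement with the definition-based oracle and
  # with stats::p.adjust
  set.seed(2)
  for (i in 1:200) {
    p <- sample(seq(0, 1, by = 0.01), sample(1:6, 1), replace = TRUE)
    a <- holm_adjust(p)
    expect_identical(a, holm_oracle(p))
    expect_equal(a, stats::p.adjust(p, method = "holm"))
  }
  # sandwich property: between Bonferroni/m-step lower bound and Bonferroni
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    a <- holm_adjust(p)
    expect_true(all(a <= pmin(1, length(p) * p) + 1e-15))
    expect_true(all(a >= p - 1e-15))
  }
})

test_that("fixed-effects-only fits reduce to OLS cell means", {
  d <- eq2_sim(n_geno = 4, n_set = 3, n_rep = 4, sigma_g = 0, seed = 5)
  d$mechanism <- d$genotype  # one-way layout on mechanism
  fit <- plastinorm:::fit_mixed_formula("M - 1",
                                        character(0),
                                        plastinorm:::prepare_anova_data(d))
  cellmeans <- as.numeric(tapply(d$rate, d$genotype, mean))
  expect_equal(sort(unname(coef(fit$fit))), sort(cellmeans),
               tolerance = 1e-10)
})

test_that("two-group balanced F equals the squared pooled t statistic", {
  set.seed(8)
  d <- data.frame(genotype = rep(c("a", "b"), each = 12),
                  mechanism = rep(c("a", "b"), each = 12),
                  env_param = "temperature", setting = 25, replicate = 1:12,
                  rate = rnorm(24, rep(c(3, 3.4), each = 12), 0.3))
  fit <- plastinorm:::fit_mixed_formula("M", character(0),
                                        plastinorm:::prepare_anova_data(d))
  tt <- type3_tests(fit)
  tstat <- stats::t.test(rate ~ mechanism, d, var.equal = TRUE)$statistic
  expect_equal(tt$F_value, unname(tstat)^2, tolerance = 1e-8)
  expect_equal(tt$df2, 22)
})

test_that("Satterthwaite df are exact on a balanced randomized block design", {
  set.seed(3)
  a <- 4; b <- 8
  d <- expand.grid(A = factor(1:a), block = factor(1:b))
  d$rate <- rnorm(nrow(d), as.numeric(d$A) * 0.5 + rep(rnorm(b, 0, 1),
                                                       each = a), 0.5)
  fit <- plastinorm:::fit_mixed_formula("A", "(1 | block)", d)
  tt <- type3_tests(fit)
  # closed-form oracle: classical mixed ANOVA on mean squares
  m <- anova(stats::lm(rate ~ A + block, d))
  expect_equal(tt$F_value, m["A", "F value"], tolerance = 1e-6)
  expect_equal(tt$df2, (a - 1) * (b - 1), tolerance = 1e-4)
  expect_equal(tt$df1, a - 1)
})

test_that("Type III F is invariant to the order of the fixed terms", {
  d <- eq2_sim(n_geno = 6, n_set = 4, n_rep = 2, seed = 9)
  pd <- plastinorm:::prepare_anova_data(d)
  f1 <- plastinorm:::fit_mixed_formula("M + E + M:E", "(1 | G)", pd)
  f2 <- plastinorm:::fit_mixed_formula("E + M + E:M", "(1 | G)", pd)
  t1 <- type3_tests(f1); t2 <- type3_tests(f2)
  for (tm in c("M", "E")) {
    i <- match(tm, t1$term); j <- match(tm, t2$term)
    expect_equal(t1$F_value[i], t2$F_value[j], tolerance = 1e-6)
  }
  expect_equal(t1$F_value[t1$term == "M:E"], t2$F_value[t2$term == "E:M"],
               tolerance = 1e-6)
})

test_that("REML recovers a known genotype variance component", {
  est <- vapply(1:40, function(seed) {
    d <- eq2_sim(n_geno = 16, n_set = 6, n_rep = 2, sigma_g = 0.2,
                 sigma_e = 0.2, seed = 300 + seed)
    fit <- plastinorm:::fit_mixed_formula("E", "(1 | G)",
                                          plastinorm:::prepare_anova_data(d))
    as.data.frame(lme4::VarCorr(fit$fit))$vcov[1]
  }, 0)
  expect_lt(abs(mean(est) - 0.04) / 0.04, 0.3)
})

test_that("random-effect LRT behaves under null and alternative", {
  # null: sigma_G = 0 -> chi2 near zero, p not small
  pnull <- vapply(1:30, function(seed) {
    d <- eq2_sim(n_geno = 10, n_set = 4, n_rep = 2, sigma_g = 0,
                 seed = 500 + seed)
    fit <- plastinorm:::fit_mixed_formula("E", "(1 | G)",
                                          plastinorm:::prepare_anova_data(d))
    r <- lrt_random_effects(fit, "G")
    expect_gte(r$chi2, 0)  # deleting a term never improves the fit
    r$p
  }, 0)
  expect_gte(stats::median(pnull), 0.3)

  # alternative: ICC 0.5 with 26 groups x 30 obs -> overwhelming evidence
  psig <- vapply(1:20, function(seed) {
    set.seed(800 + seed)
    g <- factor(rep(1:26, each = 30))
    d <- data.frame(genotype = paste0("g", g), mechanism = "x",
                    env_param = "e", setting = 1, replicate = 1,
                    rate = rnorm(26, 0, 1)[g] + rnorm(780, 3, 1))
    fit <- plastinorm:::fit_mixed_formula("1", "(1 | G)",
                                          plastinorm:::prepare_anova_data(d))
    lrt_random_effects(fit, "G")$p
  }, 0)
  expect_gte(mean(psig < 0.001), 0.95)
})

test_that("lrt rejects unknown terms and the eq2 wrapper runs end to end", {
  d <- simulate_growth_rates(default_sim_config(seed = 12),
                             enumerate_design())
  fit <- fit_mixed_model(d, "eq2", env_param = "pH")
  expect_error(lrt_random_effects(fit, "nonsense"), "not a random term")
  tab <- type3_tests(fit)
  expect_setequal(tab$term, c("M", "E", "M:E"))
  expect_true(all(tab$F_value >= 0))
  expect_true(all(tab$df2 > 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # E has 5 numerator df and a denominator df near 100, as in the
  # per-parameter analyses of this design
  expect_equal(tab$df1[tab$term == "E"], 5)
  expect_lt(abs(tab$df2[tab$term == "E"] - 100), 5)
  rt <- random_effects_tests(fit)
  expect_setequal(rt$term, c("G", "G:E"))
  expect_true(all(rt$p_value <= 1))
})

test_that("pairwise interaction tests are calibrated and Holm-adjusted", {
  mu <- setNames(c(2, 2.5, 3, 3.2, 3, 2.5), c(15, 20, 25, 30, 35, 40))
  # single mutant: adjusted p equals raw p
  tab <- two_genotype_table(mu, mu, seed = 31)
  pw <- pairwise_control_tests(tab, "4200", "temperature")
  expect_equal(pw$p_holm, pw$p_raw)
  # pure elevation shift: interaction should NOT fire beyond its level
  pelev <- vapply(1:120, function(seed) {
    t2 <- two_genotype_table(mu, mu + 0.5, seed = 400 + seed)
    pairwise_control_tests(t2, "4200", "temperature")$p_raw
  }, 0)
  expect_lt(mean(pelev < 0.05), 0.12)
  # uniformity of the null interaction p-value (Kolmogorov-Smirnov)
  ks <- suppressWarnings(stats::ks.test(pelev, "punif"))
  expect_gt(ks$p.value, 0.01)
  # a real shape change is detected
  shape <- mu + c(0, 0, 0, 0, -1.2, -1.5)
  t3 <- two_genotype_table(mu, shape, seed = 77)
  expect_lt(pairwise_control_tests(t3, "4200", "temperature")$p_holm, 0.01)
})

test_that("the full-data model has the nested factorial structure", {
  d <- simulate_growth_rates(default_sim_config(seed = 12),
                             enumerate_design())
  fit <- fit_mixed_model(d, "eq1")
  tab <- type3_tests(fit)
  expect_setequal(tab$term, c("M", "S", "S:E", "M:S", "M:S:E"))
  # numerator df follow the nesting: settings within parameter 4*5 = 20,
  # mechanism x setting-within-parameter 5*20 = 100
  expect_equal(tab$df1[tab$term == "S:E"], 20)
  expect_equal(tab$df1[tab$term == "M:S:E"], 100)
  expect_equal(tab$df1[tab$term == "S"], 3)
  rt <- random_effects_tests(fit)
  expect_setequal(rt$term, c("G", "G:S", "G:S:E"))
  # genotype and genotype-by-setting variation are present in the generator
  expect_lt(rt$p_value[rt$term == "G"], 1e-6)
  expect_lt(rt$p_value[rt$term == "G:S:E"], 1e-6)
})

test_that("growth-chamber covariate can enter the temperature model", {
  d <- simulate_growth_rates(default_sim_config(seed = 13),
                             enumerate_design())
  d <- d[d$env_param == "temperature", ]
  d$chamber <- ifelse((d$replicate + d$setting) %% 2 == 0, "A", "B")
  fit <- fit_mixed_model(d, "eq2", env_param = "temperature",
                         extra_fixed = "chamber")
  tab <- type3_tests(fit)
  expect_true("chamber" %in% tab$term)
  expect_gt(tab$p_value[tab$term == "chamber"], 0.001)
})
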