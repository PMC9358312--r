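# Regression machinery: z-transform, binomial IRLS, beta regression,
# comparison and species contrasts.

test_that("z-standardization centers, scales, and refuses constants", {
  expect_equal(z_standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- z_standardize(rnorm(50))
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  expect_error(z_standardize(rep(2, 10), "col"), "col")
  expect_error(z_standardize(1), "at least 2")
})

test_that("intercept-only binomial fit equals the pooled logit", {
  X <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_binomial_glm(30, 100, X)
  expect_equal(f$coefficients$estimate, qlogis(0.3), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("IRLS agrees with stats::glm and a generic optimizer", {
  set.seed(101)
  n <- 60
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  trials <- rpois(n, 20) + 1
  p <- plogis(-0.4 + 0.7 * X[, "x1"] - 0.5 * X[, "x2"])
  y <- rbinom(n, trials, p)
  ours <- fit_binomial_glm(y, trials, X)
  ref <- stats::glm(cbind(y, trials - y) ~ X[, -1], family = binomial)
  expect_equal(ours$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(ours$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  # generic optimizer oracle on the same likelihood
  nll <- function(b) -sum(dbinom(y, trials, plogis(X %*% b), log = TRUE))
  opt <- optim(rep(0, 3), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(ours$coefficients$estimate, opt$par, tolerance = 1e-5)
  expect_equal(ours$aic, 2 * 3 - 2 * ours$loglik)
})

test_that("a planted logistic slope is recovered across seeded replicates", {
  est <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 400
    x <- z_standardize(rnorm(n))
    trials <- rep(1, n)
    y <- rbinom(n, trials, plogis(-0.2 + 0.30 * x))
    X <- cbind("(Intercept)" = 1, x = x)
    fit_binomial_glm(y, trials, X)$coefficients$estimate[2]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.30), 0.05)
})

test_that("complete separation is flagged, not silently reported", {
  X <- matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_binomial_glm(rep(10, 5), rep(10, 5), X)
  expect_false(f$converged)
  expect_true(f$diagnostics$separated)
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  X <- cbind("(Intercept)" = 1, a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_binomial_glm(c(1, 2, 1, 3), rep(5, 4), X), "\\bb\\b")
})

test_that("beta regression recovers planted mean structure", {
  # intercept-only on proportions centred at one half
  set.seed(7)
  y <- rbeta(150, 10, 10)
  X <- matrix(1, 150, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_beta_regression(y, X)
  expect_lt(abs(f$coefficients$estimate), 2 * f$coefficients$se)
  expect_true(all(f$fitted > 0 & f$fitted < 1))

  # planted slope 0.4 at precision 20, fifty replicates
  est <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 200
    x <- z_standardize(rnorm(n))
    mu <- plogis(0.3 + 0.4 * x)
    y <- rbeta(n, mu * 20, (1 - mu) * 20)
    X <- cbind("(Intercept)" = 1, x = x)
    fit_beta_regression(y, X)$coefficients$estimate[2]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.1)

  # boundary values are shrunk, not fatal
  yb <- c(0, 0.2, 0.5, 0.8, 1, 0.4, 0.6, 0.7)
  Xb <- matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)"))
  expect_silent(fit_beta_regression(yb, Xb))
  expect_error(fit_beta_regression(c(0.5, 1.2), matrix(1, 2, 1)), "0, 1")
})

test_that("beta regression agrees with an independent mixed-model fitter", {
  skip_if_not_installed("glmmTMB")
  set.seed(13)
  n <- 120
  x <- z_standardize(rnorm(n))
  mu <- plogis(0.2 + 0.5 * x)
  y <- rbeta(n, mu * 15, (1 - mu) * 15)
  X <- cbind("(Intercept)" = 1, x = x)
  ours <- fit_beta_regression(y, X)
  dat <- data.frame(y = y, x = x)
  ref <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::beta_family(), data = dat)
  expect_equal(ours$coefficients$estimate,
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
})

test_that("model comparison ranks by AIC and checks unit identity", {
  set.seed(5)
  n <- 80
  x <- rnorm(n)
  trials <- rep(10, n)
  y <- rbinom(n, trials, plogis(0.8 * scale(x)[, 1]))
  X1 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X2 <- cbind("(Intercept)" = 1, x = scale(x)[, 1])
  f1 <- fit_binomial_glm(y, trials, X1, name = "control")
  f2 <- fit_binomial_glm(y, trials, X2, name = "full")
  tab <- compare_models(list(f1, f2), kfold = 5, seed = 3)
  expect_true(tab$best[tab$model == "full"])
  expect_equal(tab$delta_aic[tab$model == "full"], 0)
  expect_lt(tab$cv_diff[2], 0)  # full predicts held-out data better

  self_tab <- compare_models(list(f2, f2))
  expect_equal(self_tab$delta_aic, c(0, 0))

  f3 <- fit_binomial_glm(rev(y), trials, X1, name = "other")
  expect_error(compare_models(list(f1, f3)), "same response")
})

test_that("species contrasts produce all pairwise comparisons or fail early", {
  a <- analyze_dataset(cfg = small_config(), seed = 41)
  r <- a$suite[["M4-Ind"]]
  ctr <- species_contrasts(r$fit)
  expect_equal(nrow(ctr$contrasts), 3)
  expect_setequal(ctr$means$species, c("chimpanzee", "orangutan", "siamang"))
  expect_true(all(ctr$means$prob > 0 & ctr$means$prob < 1))
  # control fit has no species term
  expect_error(species_contrasts(a$suite[["M4-Ind"]]$fits$control),
               "species")
  expect_error(species_contrasts(r$fit, species_levels = "gorilla"), "absent")
})

test_that("the model suite fits all ten specs with their structure", {
  a <- analyze_dataset(cfg = small_config(), seed = 42)
  expect_length(a$suite, 10)
  expect_setequal(names(a$suite),
                  vapply(default_model_specs(), function(s) s$name, ""))
  m2 <- a$suite[["M2-Ind"]]$fit
  expect_true("modalityvisual:z_age" %in% m2$coefficients$term)
  expect_true(all(vapply(a$suite, function(r) r$fit$converged, TRUE)))
  expect_equal(nrow(a$summary), 14)
  # a spec naming a missing column fails before fitting
  bad <- default_model_specs()[1]
  bad[[1]]$full <- c(bad[[1]]$full, "no_such_column")
  expect_error(run_model_suite(a$ind_table, a$dy_table, specs = bad),
               "no_such_column")
})

test_that("dyad bootstrap replaces Fisher standard errors when requested", {
  a <- analyze_dataset(cfg = small_config(), seed = 43)
  suite <- run_model_suite(a$ind_table, a$dy_table, boot = 40, seed = 9)
  tab <- suite[["M1-Dyad"]]$fit$coefficients
  expect_true("model_se" %in% names(tab))
  expect_true(all(tab$se > 0))
  # intervals rebuilt from the bootstrap SEs
  expect_equal(tab$upper - tab$estimate, 1.96 * tab$se, tolerance = 1e-10)
})
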