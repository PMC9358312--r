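# Regression machinery for the M1-M5 model families: binomial GLMs fitted
# by iteratively reweighted least squares and beta regression fitted by
# quasi-Newton maximum likelihood. Deterministic ML stand-ins for the
# Bayesian flat-prior fits such analyses are often run with: with flat
# priors the posterior mode coincides with the ML estimate, so coefficients
# and Wald intervals are directly comparable.

#' z-standardize a numeric vector
#'
#' Centers and scales to unit standard deviation (denominator `n - 1`), the
#' transformation applied to every continuous predictor and control before
#' model fitting so that coefficients are comparable across predictors.
#'
#' @param values numeric vector, length at least 2.
#' @param name column name used in error messages.
#' @return Numeric vector with mean 0 and sd 1.
#' @examples
#' z_standardize(c(1, 2, 3))
#' @export
z_standardize <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2) stop("z_standardize needs at least 2 values: ", name)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-standardize constant column: ", name)
  }
  (values - mean(values)) / s
}

check_design <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design matrix; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

new_model_fit <- function(name, family, coef, vcov, loglik, n_units, converged,
                          diagnostics = NULL, extra = list()) {
  est <- coef
  se <- sqrt(pmax(diag(vcov), 0))
  k <- length(est) + (if (family == "beta") 1L else 0L)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    lower = unname(est - 1.96 * se),
                    upper = unname(est + 1.96 * se),
                    stringsAsFactors = FALSE)
  structure(c(list(name = name, family = family, coefficients = tab,
                   vcov = vcov, loglik = loglik, aic = 2 * k - 2 * loglik,
                   n_units = n_units, converged = converged,
                   diagnostics = diagnostics), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<model_fit> %s (%s), n = %d, logLik = %.2f, AIC = %.2f%s\n",
              x$name, x$family, x$n_units, x$loglik, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Binomial GLM with logit link, fitted by IRLS
#'
#' Maximum-likelihood logistic regression for aggregated binomial counts,
#' fitted by iteratively reweighted least squares; standard errors come from
#' the inverse Fisher information at the optimum. Complete separation (or
#' any failure to converge within `max_iter` iterations) does not raise an
#' error: the fit is returned with `converged = FALSE` and diagnostics, so
#' a model suite can report it rather than die.
#'
#' @param successes,trials integer vectors, `0 <= successes <= trials`.
#' @param X design matrix (full rank; include the intercept column).
#' @param name label carried into the fit object.
#' @param max_iter,tol IRLS iteration cap and deviance-change tolerance.
#' @return A `model_fit` object: coefficient table (estimate, SE, Wald 95%
#'   interval), log-likelihood, AIC, convergence flag, fitted values.
#' @examples
#' f <- fit_binomial_glm(30, 100, matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")))
#' f$coefficients$estimate  # logit(0.3)
#' @export
fit_binomial_glm <- function(successes, trials, X, name = "binomial_glm",
                             max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(successes < 0) || any(successes > trials) || any(trials < 1)) {
    stop("need 0 <= successes <= trials and trials >= 1")
  }
  if (length(successes) != nrow(X) || length(trials) != nrow(X)) {
    stop("successes, trials and design matrix disagree in length")
  }
  check_design(X)
  y <- successes / trials
  mu <- (successes + 0.5) / (trials + 1)
  eta <- stats::qlogis(mu)
  dev_old <- Inf
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- trials * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- as.vector(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(stats::dbinom(successes, trials, mu, log = TRUE))
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  # complete separation: fitted probabilities pinned to the boundary
  separated <- any(abs(eta) >= 29.9)
  if (separated) converged <- FALSE
  W <- trials * mu * (1 - mu)
  info <- crossprod(X, X * W)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  loglik <- sum(stats::dbinom(successes, trials, mu, log = TRUE))
  names(beta) <- colnames(X)
  new_model_fit(name, "binomial", beta, vcov, loglik,
                n_units = nrow(X), converged = converged,
                diagnostics = if (!converged)
                  list(separated = separated, iterations = it,
                       max_abs_eta = max(abs(eta))) else NULL,
                extra = list(fitted = mu, successes = successes,
                             trials = trials, X = X))
}

#' Beta regression with logit mean link
#'
#' Models proportions in (0, 1) with a beta distribution parameterized by
#' mean `mu = plogis(X beta)` and a constant precision `phi`
#' (`shape1 = mu * phi`, `shape2 = (1 - mu) * phi`), jointly maximizing the
#' likelihood over `(beta, log phi)` by BFGS quasi-Newton ascent. Standard
#' errors come from the observed information (numerical Hessian at the
#' optimum). Observations exactly on the boundary are shrunk with the
#' Smithson-Verkuilen transformation `y' = (y (n - 1) + 0.5) / n` before
#' fitting.
#'
#' @param proportions numeric vector in `[0, 1]`.
#' @param X design matrix (full rank, intercept included).
#' @param name label carried into the fit object.
#' @return A `model_fit` object; the precision estimate is stored as
#'   `phi` (with `log_phi_se`).
#' @export
fit_beta_regression <- function(proportions, X, name = "beta_regression") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- proportions
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  if (length(y) != nrow(X)) stop("proportions and design matrix disagree in length")
  check_design(X)
  n <- length(y)
  if (any(y <= 0) || any(y >= 1)) {
    y <- (y * (n - 1) + 0.5) / n
  }
  p <- ncol(X)
  beta0 <- tryCatch(stats::lm.fit(X, stats::qlogis(y))$coefficients,
                    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  mu0 <- stats::plogis(as.vector(X %*% beta0))
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-6) - 1, 2)
  nll <- function(par) {
    mu <- stats::plogis(pmin(pmax(as.vector(X %*% par[1:p]), -30), 30))
    phi <- exp(pmin(par[p + 1], 20))
    ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(c(beta0, log(phi0)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  converged <- opt$convergence == 0
  vcov_all <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, p + 1, p + 1)
  })
  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  vcov <- vcov_all[1:p, 1:p, drop = FALSE]
  dimnames(vcov) <- list(colnames(X), colnames(X))
  mu_hat <- stats::plogis(as.vector(X %*% beta))
  new_model_fit(name, "beta", beta, vcov, -opt$value,
                n_units = n, converged = converged,
                diagnostics = if (!converged) list(optim_code = opt$convergence) else NULL,
                extra = list(fitted = mu_hat, y = y,
                             phi = exp(opt$par[p + 1]),
                             log_phi_se = sqrt(max(vcov_all[p + 1, p + 1], 0)),
                             X = X))
}

refit_model <- function(fit, idx_train) {
  X <- fit$X[idx_train, , drop = FALSE]
  keep <- qr(X)$rank == ncol(X)
  if (!keep) return(NULL)
  if (fit$family == "binomial") {
    fit_binomial_glm(fit$successes[idx_train], fit$trials[idx_train], X,
                     name = fit$name)
  } else {
    fit_beta_regression(fit$y[idx_train], X, name = fit$name)
  }
}

heldout_deviance <- function(fit, trained, idx_test) {
  X <- fit$X[idx_test, , drop = FALSE]
  eta <- pmin(pmax(as.vector(X %*% trained$coefficients$estimate), -30), 30)
  mu <- stats::plogis(eta)
  if (fit$family == "binomial") {
    -2 * sum(stats::dbinom(fit$successes[idx_test], fit$trials[idx_test],
                           mu, log = TRUE))
  } else {
    phi <- trained$phi
    -2 * sum(stats::dbeta(fit$y[idx_test], mu * phi, (1 - mu) * phi, log = TRUE))
  }
}

#' Compare nested model fits on the same response
#'
#' Information-criterion comparison of fits sharing one response vector:
#' reports each model's log-likelihood, AIC and AIC difference from the
#' best model, flags the best (lowest-AIC) model, and optionally adds a
#' seeded k-fold cross-validated deviance with the standard error of each
#' model's per-fold deviance difference from the first (reference) fit.
#'
#' @param fits list of `model_fit` objects on identical units.
#' @param kfold number of CV folds (0 to skip CV).
#' @param seed integer seed for the fold split.
#' @return Data frame with one row per model: `model`, `loglik`, `aic`,
#'   `delta_aic`, `best`, and when `kfold > 0` also `cv_deviance`,
#'   `cv_diff`, `cv_diff_se`.
#' @export
compare_models <- function(fits, kfold = 0L, seed = 1L) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "model_fit")))
  n <- fits[[1]]$n_units
  resp <- if (fits[[1]]$family == "binomial") fits[[1]]$successes else fits[[1]]$y
  for (f in fits[-1]) {
    r <- if (f$family == "binomial") f$successes else f$y
    if (f$n_units != n || !isTRUE(all.equal(r, resp))) {
      stop("fits must share the same response vector and units")
    }
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  tab <- data.frame(
    model = vapply(fits, function(f) f$name, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = aic,
    delta_aic = aic - min(aic),
    best = aic == min(aic),
    stringsAsFactors = FALSE)
  if (kfold > 0) {
    set.seed(seed)
    k <- min(kfold, n)
    folds <- sample(rep_len(seq_len(k), n))
    dev_fold <- matrix(NA_real_, k, length(fits))
    for (fold in seq_len(k)) {
      test <- which(folds == fold)
      train <- which(folds != fold)
      for (j in seq_along(fits)) {
        tr <- refit_model(fits[[j]], train)
        dev_fold[fold, j] <- if (is.null(tr)) NA_real_
          else heldout_deviance(fits[[j]], tr, test)
      }
    }
    tab$cv_deviance <- colSums(dev_fold)
    diffs <- dev_fold - dev_fold[, 1]
    tab$cv_diff <- colSums(diffs)
    tab$cv_diff_se <- apply(diffs, 2, function(x) stats::sd(x) * sqrt(k))
  }
  tab
}

#' Post-hoc species contrasts on the link and response scales
#'
#' Estimated marginal proportions per species at the means of the numeric
#' covariates (factors averaged over their observed distribution), with all
#' pairwise link-scale differences and delta-method standard errors.
#'
#' @param fit a `model_fit` produced by [run_model_suite()] (the fit must
#'   carry its model frame and contain species terms).
#' @param species_levels optional character vector restricting/ordering the
#'   species compared.
#' @return List with `means` (species, link estimate, SE, response-scale
#'   probability with 95% interval) and `contrasts` (species_1, species_2,
#'   link-scale difference, SE, z).
#' @export
species_contrasts <- function(fit, species_levels = NULL) {
  if (is.null(fit$data) || is.null(fit$rhs)) {
    stop("fit carries no model frame; refit through run_model_suite()")
  }
  if (!"species" %in% all.vars(fit$rhs) ||
      !any(grepl("^species", fit$coefficients$term))) {
    stop("fit contains no species term")
  }
  data <- fit$data
  levs <- levels(factor(data$species))
  if (!is.null(species_levels)) {
    if (!all(species_levels %in% levs)) {
      stop("species absent from fit: ",
           paste(setdiff(species_levels, levs), collapse = ", "))
    }
    levs <- species_levels
  }
  beta <- fit$coefficients$estimate
  V <- fit$vcov
  num_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  grid_row <- function(sp) {
    nd <- data
    nd$species <- factor(sp, levels = levels(factor(data$species)))
    for (cn in num_cols) nd[[cn]] <- mean(data[[cn]])
    X <- stats::model.matrix(fit$rhs, nd, xlev = fit$xlev)
    colMeans(X[, fit$coefficients$term, drop = FALSE])
  }
  xs <- vapply(levs, grid_row, numeric(length(beta)))
  est <- as.vector(crossprod(xs, beta))
  se <- sqrt(pmax(colSums(xs * (V %*% xs)), 0))
  means <- data.frame(species = levs, link = est, se = se,
                      prob = stats::plogis(est),
                      prob_lower = stats::plogis(est - 1.96 * se),
                      prob_upper = stats::plogis(est + 1.96 * se),
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(levs), 2)
  ctr <- apply(pairs, 2, function(ij) {
    g <- xs[, ij[1]] - xs[, ij[2]]
    d <- sum(g * beta)
    s <- sqrt(max(sum(g * (V %*% g)), 0))
    c(d, s)
  })
  contrasts <- data.frame(
    species_1 = levs[pairs[1, ]], species_2 = levs[pairs[2, ]],
    difference = ctr[1, ], se = ctr[2, ], z = ctr[1, ] / ctr[2, ],
    stringsAsFactors = FALSE)
  list(means = means, contrasts = contrasts)
}
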