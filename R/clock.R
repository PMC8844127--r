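# The metabolome clock: an elastic-net regression of chronological age
# on metabolite profiles, with the loss
#   (1/2N) sum_i (y_i - b0 - x_i' b)^2
#     + lambda2 * ( (1 - lambda1) ||b||^2 / 2 + lambda1 ||b||_1 )
# (lambda1 = 0 is ridge, lambda1 = 1 is lasso, lambda1 = lambda2 = 0 is
# OLS; the intercept is never penalized).  Solved by covariance-update
# coordinate descent in compiled code.  Residuals of leave-one-out
# predictions define per-sample age acceleration.

enet_prepare <- function(X, y) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  list(G = crossprod(Xc) / n, b = drop(crossprod(Xc, yc)) / n,
       syy = sum(yc^2) / n, xbar = xbar, ybar = ybar, n = n)
}

#' Hyperparameter schedule for clock tuning
#'
#' Defaults follow the standard tuning protocol for a metabolome clock:
#' the mixing parameter `lambda1` searched over 0, 0.1, ..., 1.0; the
#' regularization `lambda2` over 100 values evenly spaced in
#' `[1e-6, 1]` plus 1000 values evenly spaced in `[1, 1000]` (linear
#' spacing); 100 random 80/20 train/test splits, each tuned by 5-fold
#' cross-validation inside the training set.
#'
#' @param lambda1_grid Mixing values in `[0, 1]`.
#' @param lambda2_grid Regularization values `>= 0`.
#' @param n_repeats Number of train/test repeats.
#' @param test_fraction Held-out fraction per repeat.
#' @param cv_folds Folds for the inner cross-validation.
#' @param seed Seed governing all splits.
#' @return A list of class `"clock_hyperparams"`.
#' @export
clock_hyperparams <- function(lambda1_grid = seq(0, 1, by = 0.1),
                              lambda2_grid = c(seq(1e-6, 1, length.out = 100),
                                               seq(1, 1000, length.out = 1000)),
                              n_repeats = 100L, test_fraction = 0.2,
                              cv_folds = 5L, seed = NULL) {
  if (length(lambda1_grid) == 0 || length(lambda2_grid) == 0)
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  if (any(lambda1_grid < 0 | lambda1_grid > 1))
    stop("lambda1 values must lie in [0, 1]", call. = FALSE)
  if (any(lambda2_grid < 0)) stop("lambda2 values must be >= 0", call. = FALSE)
  structure(list(lambda1_grid = lambda1_grid,
                 lambda2_grid = sort(unique(lambda2_grid)),
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds), seed = seed),
            class = "clock_hyperparams")
}

#' Fit an elastic-net age model at fixed tuning values
#'
#' Minimizes the elastic-net objective (see above) by coordinate
#' descent; features enter as-is (samples are already row-standardized
#' by [preprocess()]), and the intercept is unpenalized.
#'
#' @param X Sample-by-metabolite matrix (no missing values).
#' @param y Chronological ages in days.
#' @param lambda1 Mixing parameter in `[0, 1]`.
#' @param lambda2 Regularization parameter `>= 0`.
#' @param tol Coordinate-change convergence tolerance.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @return A `clock_model`: intercept (days), named coefficient vector
#'   (days per normalized unit), tuning values, and the achieved
#'   objective `training_loss`.
#' @export
elastic_net_fit <- function(X, y, lambda1, lambda2, tol = 1e-9,
                            max_iter = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in X or y", call. = FALSE)
  if (lambda1 < 0 || lambda1 > 1) stop("lambda1 must be in [0, 1]", call. = FALSE)
  if (lambda2 < 0) stop("lambda2 must be >= 0", call. = FALSE)
  pr <- enet_prepare(X, y)
  sol <- elnet_gram_path(pr$G, pr$b, pr$syy, lambda1, lambda2,
                         numeric(ncol(X)), tol, max_iter)
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  structure(list(intercept = pr$ybar - sum(pr$xbar * beta),
                 coefficients = beta, lambda1 = lambda1, lambda2 = lambda2,
                 training_loss = sol$objective[1],
                 iterations = sol$iterations[1],
                 converged = sol$converged[1]),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("metabolome clock: lambda1 = %g, lambda2 = %g, %d/%d nonzero coefficients\n",
              x$lambda1, x$lambda2, sum(x$coefficients != 0),
              length(x$coefficients)))
  cat(sprintf("  intercept %.2f d, objective %.6g\n", x$intercept,
              x$training_loss))
  invisible(x)
}

#' @export
predict.clock_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  nm <- names(object$coefficients)
  if (!is.null(colnames(newdata)) && !is.null(nm) &&
      all(nm %in% colnames(newdata)))
    newdata <- newdata[, nm, drop = FALSE]
  drop(newdata %*% object$coefficients) + object$intercept
}

#' Elastic-net objective value
#'
#' Evaluates the clock loss at given parameters; used for reporting and
#' for independent verification of fits.
#'
#' @param X,y Data as in [elastic_net_fit()].
#' @param intercept,beta Model parameters.
#' @param lambda1,lambda2 Tuning values.
#' @return The objective value.
#' @export
enet_objective <- function(X, y, intercept, beta, lambda1, lambda2) {
  r <- y - intercept - drop(as.matrix(X) %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda2 * ((1 - lambda1) * sum(beta^2) / 2 + lambda1 * sum(abs(beta)))
}

r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

# Fit the whole lambda2 path (descending, warm-started) on a training
# subset and return validation MSE for every lambda2.
cv_path_mse <- function(Xtr, ytr, Xval, yval, lambda1, l2_desc, tol, max_iter) {
  pr <- enet_prepare(Xtr, ytr)
  sol <- elnet_gram_path(pr$G, pr$b, pr$syy, lambda1, l2_desc,
                         numeric(ncol(Xtr)), tol, max_iter)
  B <- sol$beta
  b0 <- pr$ybar - drop(crossprod(pr$xbar, B))
  pred <- sweep(Xval %*% B, 2, b0, "+")
  colMeans((pred - yval)^2)
}

#' Tune and evaluate the clock by repeated train/test splits
#'
#' For each repeat the samples are split at random into training
#' (`1 - test_fraction`) and testing sets; `(lambda1, lambda2)` is
#' selected by mean squared error over `cv_folds`-fold cross-validation
#' within the training set; the selected model is refit on the full
#' training set and scored as R-squared on the test set.  The
#' consensus hyperparameters are the grid pair minimizing the mean CV
#' error across all repeats (the per-repeat modal pair is also
#' reported).
#'
#' @param mat A normalized [metabolite_matrix()] (ages are taken from
#'   the sample metadata).
#' @param hp A [clock_hyperparams()].
#' @param tol,max_iter Solver controls.
#' @return A list with `results` (per-repeat data frame: `rep`,
#'   `lambda1`, `lambda2`, `test_r2`), `consensus` (list with `lambda1`,
#'   `lambda2`), `modal` (most frequently selected per-repeat pair), and
#'   `cv_mean` (mean CV-MSE over the grid).
#' @export
tune_and_evaluate <- function(mat, hp = clock_hyperparams(), tol = 1e-7,
                              max_iter = 100000L) {
  X <- mat$values
  y <- mat$samples$age_day
  n <- nrow(X)
  if (n < 30L) stop("need at least 30 samples to tune", call. = FALSE)
  if (!is.null(hp$seed)) set.seed(hp$seed)
  l1g <- hp$lambda1_grid
  l2_desc <- sort(hp$lambda2_grid, decreasing = TRUE)
  cv_sum <- matrix(0, length(l1g), length(l2_desc))
  results <- vector("list", hp$n_repeats)
  for (r in seq_len(hp$n_repeats)) {
    test_idx <- sample.int(n, max(1L, round(n * hp$test_fraction)))
    tr <- setdiff(seq_len(n), test_idx)
    fold <- sample(rep_len(seq_len(hp$cv_folds), length(tr)))
    cv <- matrix(0, length(l1g), length(l2_desc))
    for (f in seq_len(hp$cv_folds)) {
      itr <- tr[fold != f]
      ival <- tr[fold == f]
      for (a in seq_along(l1g)) {
        cv[a, ] <- cv[a, ] +
          cv_path_mse(X[itr, , drop = FALSE], y[itr],
                      X[ival, , drop = FALSE], y[ival],
                      l1g[a], l2_desc, tol, max_iter) / hp$cv_folds
      }
    }
    cv_sum <- cv_sum + cv
    pick <- arrayInd(which.min(cv), dim(cv))
    l1 <- l1g[pick[1]]
    l2 <- l2_desc[pick[2]]
    fit <- elastic_net_fit(X[tr, , drop = FALSE], y[tr], l1, l2,
                           tol = tol, max_iter = max_iter)
    yhat <- predict(fit, X[test_idx, , drop = FALSE])
    results[[r]] <- data.frame(rep = r, lambda1 = l1, lambda2 = l2,
                               test_r2 = r_squared(y[test_idx], yhat))
  }
  results <- do.call(rbind, results)
  cv_mean <- cv_sum / hp$n_repeats
  pick <- arrayInd(which.min(cv_mean), dim(cv_mean))
  sel <- paste(results$lambda1, results$lambda2)
  modal <- strsplit(names(which.max(table(sel))), " ")[[1]]
  list(results = results,
       consensus = list(lambda1 = l1g[pick[1]], lambda2 = l2_desc[pick[2]]),
       modal = list(lambda1 = as.numeric(modal[1]),
                    lambda2 = as.numeric(modal[2])),
       cv_mean = cv_mean, lambda1_grid = l1g, lambda2_grid = l2_desc)
}

#' Leave-one-out predicted ages
#'
#' Predicts each sample's age from a clock fitted to all other samples
#' at fixed hyperparameters (chosen before LOOCV), so no sample
#' influences its own prediction.  Cross-moment matrices are downdated
#' per left-out sample, with warm-started coordinate descent.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @param lambda1,lambda2 Tuning values (e.g. the consensus pair from
#'   [tune_and_evaluate()]).
#' @param tol,max_iter Solver controls.
#' @return A data frame `sample_id`, `genotype`, `age_day`,
#'   `predicted_age`.
#' @export
loocv_predict <- function(mat, lambda1, lambda2, tol = 1e-9,
                          max_iter = 100000L) {
  X <- mat$values
  y <- mat$samples$age_day
  n <- nrow(X)
  S <- crossprod(X)
  sx <- colSums(X)
  sxy <- drop(crossprod(X, y))
  sumy <- sum(y)
  sumy2 <- sum(y^2)
  pred <- numeric(n)
  warm <- numeric(ncol(X))
  for (i in seq_len(n)) {
    xi <- X[i, ]
    yi <- y[i]
    n1 <- n - 1
    m1 <- (sx - xi) / n1
    ybar1 <- (sumy - yi) / n1
    G <- (S - tcrossprod(xi) - n1 * tcrossprod(m1)) / n1
    b <- (sxy - xi * yi - n1 * m1 * ybar1) / n1
    syy <- (sumy2 - yi^2) / n1 - ybar1^2
    sol <- elnet_gram_path(G, b, syy, lambda1, lambda2, warm, tol, max_iter)
    beta <- drop(sol$beta)
    warm <- beta
    pred[i] <- (ybar1 - sum(m1 * beta)) + sum(xi * beta)
  }
  data.frame(sample_id = mat$samples$sample_id,
             genotype = mat$samples$genotype,
             age_day = y, predicted_age = pred, stringsAsFactors = FALSE)
}

#' Age acceleration
#'
#' The difference between the predicted and the chronological age of
#' each sample; positive values mean the sample reads as biologically
#' older than its chronological age.
#'
#' @param predictions Data frame from [loocv_predict()] (columns
#'   `sample_id`, `genotype`, `age_day`, `predicted_age`).
#' @return The input with a `theta` column (`predicted_age - age_day`),
#'   plus an attribute `genotype_age_means` holding the genotype-by-age
#'   mean accelerations.
#' @export
age_acceleration <- function(predictions) {
  out <- predictions
  out$theta <- out$predicted_age - out$age_day
  gm <- stats::aggregate(theta ~ genotype + age_day, data = out, FUN = mean)
  attr(out, "genotype_age_means") <- gm
  out
}

#' Age acceleration versus demographic parameters
#'
#' Regresses each demographic parameter (mean lifespan, `ln(alpha)`,
#' `beta`, and any fitted `hazard_d*` columns) on the genotype-mean age
#' acceleration at the chosen age, reporting the linear-model slope and
#' p-value alongside Spearman's rho.
#'
#' @param aa Output of [age_acceleration()].
#' @param demography Demography table (see [demography_table()]).
#' @param at_age Age (days) at which to take genotype-mean
#'   acceleration.
#' @return A data frame `parameter`, `estimate`, `p`, `rho`, `rho_p`,
#'   `n_genotypes`.
#' @export
aa_demography_assoc <- function(aa, demography, at_age = 45) {
  gm <- attr(aa, "genotype_age_means")
  if (is.null(gm))
    gm <- stats::aggregate(theta ~ genotype + age_day, data = aa, FUN = mean)
  gm <- gm[gm$age_day == at_age, , drop = FALSE]
  if (nrow(gm) == 0) stop(sprintf("no samples at age %g", at_age), call. = FALSE)
  idx <- match(gm$genotype, demography$genotype)
  if (anyNA(idx)) stop("demography table is missing genotypes", call. = FALSE)
  if (nrow(gm) < 5L) stop("need >= 5 genotypes", call. = FALSE)
  theta <- gm$theta
  pars <- c("mean_lifespan", "ln_alpha", "beta",
            grep("^hazard_d", names(demography), value = TRUE))
  rows <- lapply(pars, function(par) {
    phi <- demography[[par]][idx]
    if (sd(theta) == 0) {
      warning("age acceleration is constant; association undefined",
              call. = FALSE)
      return(data.frame(parameter = par, estimate = NA_real_, p = NA_real_,
                        rho = NA_real_, rho_p = NA_real_,
                        n_genotypes = nrow(gm), stringsAsFactors = FALSE))
    }
    sm <- summary(lm(phi ~ theta))
    sc <- spearman_cor(theta, phi)
    data.frame(parameter = par,
               estimate = sm$coefficients["theta", "Estimate"],
               p = sm$coefficients["theta", "Pr(>|t|)"],
               rho = sc$rho, rho_p = sc$p, n_genotypes = nrow(gm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
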