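# Demographic estimation from interval-censored death tables: the
# Gompertz-Makeham hazard mu(x) = alpha * exp(beta * x) + M, its survival
# function, exact interval-censored maximum likelihood, Kaplan-Meier
# restricted means, log-rank tests, and cross-genotype diagnostics.

#' Construct a Gompertz--Makeham fit object
#'
#' @param alpha,beta,makeham Hazard parameters (day^-1).
#' @param log_likelihood Achieved log-likelihood (NA for hand-built fits).
#' @param converged Logical convergence flag.
#' @param n_obs Number of deaths the fit is based on.
#' @return An object of class `"gm_fit"`.
#' @export
gm_fit <- function(alpha, beta, makeham = 0, log_likelihood = NA_real_,
                   converged = NA, n_obs = NA_integer_) {
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (beta < 0 || makeham < 0)
    stop("'beta' and 'makeham' must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, makeham = makeham,
                 log_likelihood = log_likelihood, converged = converged,
                 n_obs = n_obs), class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham fit: ln(alpha) = %.3f, beta = %.4f, M = %.4g\n",
              log(x$alpha), x$beta, x$makeham))
  if (is.finite(x$log_likelihood))
    cat(sprintf("  log-likelihood %.3f on %d deaths (converged: %s)\n",
                x$log_likelihood, x$n_obs, x$converged))
  invisible(x)
}

as_gm_par <- function(fit) {
  if (inherits(fit, "gm_fit") || (is.list(fit) &&
      all(c("alpha", "beta") %in% names(fit)))) {
    list(alpha = fit$alpha, beta = fit$beta, makeham = fit$makeham %||% 0)
  } else stop("expected a 'gm_fit' or a list with alpha/beta/makeham",
              call. = FALSE)
}

#' Gompertz--Makeham hazard and survival functions
#'
#' `gm_hazard()` evaluates the instantaneous mortality rate
#' `alpha * exp(beta * x) + M`; `gm_survival()` evaluates its closed-form
#' survival function `S(x) = exp(-M x - (alpha/beta) (exp(beta x) - 1))`
#' (with the exponential limit `exp(-(alpha + M) x)` when `beta = 0`).
#'
#' @param fit A [gm_fit()] (or list with `alpha`, `beta`, `makeham`).
#' @param x Age(s) in days, `>= 0`.
#' @return Hazard in day^-1, or survival probability in `[0, 1]`.
#' @examples
#' f <- gm_fit(exp(-11.5), 0.115)
#' gm_hazard(f, 0)    # exp(-11.5)
#' gm_survival(f, 0)  # 1
#' @export
gm_hazard <- function(fit, x) {
  p <- as_gm_par(fit)
  if (any(x < 0)) stop("age 'x' must be >= 0", call. = FALSE)
  p$alpha * exp(p$beta * x) + p$makeham
}

#' @rdname gm_hazard
#' @export
gm_survival <- function(fit, x) {
  p <- as_gm_par(fit)
  if (any(x < 0)) stop("age 'x' must be >= 0", call. = FALSE)
  if (p$beta > 0) {
    exp(-p$makeham * x - (p$alpha / p$beta) * expm1(p$beta * x))
  } else {
    exp(-(p$alpha + p$makeham) * x)
  }
}

# Collapse a death table to unique intervals (vials pooled).
collapse_intervals <- function(deaths) {
  agg <- stats::aggregate(n_dead ~ interval_start + interval_end,
                          data = as.data.frame(deaths), FUN = sum)
  agg[order(agg$interval_start), , drop = FALSE]
}

censored_of <- function(deaths) {
  if (!is.null(deaths$n_censored) && any(deaths$n_censored > 0)) {
    agg <- stats::aggregate(n_censored ~ interval_end,
                            data = as.data.frame(deaths), FUN = sum)
    agg[agg$n_censored > 0, , drop = FALSE]
  } else NULL
}

# Interval-censored GM log-likelihood:
#   sum_intervals n_dead * log(S(start) - S(end)) + sum_cens log S(t_c)
gm_interval_loglik <- function(alpha, beta, makeham, intervals, censored = NULL) {
  par <- list(alpha = alpha, beta = beta, makeham = makeham)
  s0 <- gm_survival(par, intervals$interval_start)
  s1 <- gm_survival(par, intervals$interval_end)
  pr <- s0 - s1
  if (any(pr <= 0)) return(-Inf)
  ll <- sum(intervals$n_dead * log(pr))
  if (!is.null(censored)) {
    sc <- gm_survival(par, censored$interval_end)
    if (any(sc <= 0)) return(-Inf)
    ll <- ll + sum(censored$n_censored * log(sc))
  }
  ll
}

#' Fit the Gompertz--Makeham model to an interval-censored death table
#'
#' Maximizes the exact interval-censored log-likelihood
#' `sum n_dead * log(S(start) - S(end))` (plus `log S(t)` terms for any
#' censored flies) over `(ln alpha, ln beta, ln M)`; `M` is fixed at 0
#' when `include_makeham = FALSE`, giving the pure Gompertz model.
#' Optimization is multi-start: `(ln alpha, beta)` are seeded by least
#' squares on the log empirical interval hazard against age, `M` at half
#' the earliest-interval empirical hazard, with fixed fallback starts;
#' each start is polished by Nelder--Mead then BFGS.
#'
#' @param deaths A `death_table` (one genotype).
#' @param include_makeham Fit the age-independent term `M > 0`?  The
#'   default follows the convention of allowing extra early-age
#'   mortality; turn off for analyses phrased purely in `alpha`/`beta`.
#' @return A [gm_fit()] with the achieved log-likelihood.
#' @examples
#' d <- simulate_gm_deaths(genotype_spec("G", exp(-11.5), 0.115,
#'                         n_vials = 8, flies_per_vial = 25), seed = 1)
#' fit_gm(d, include_makeham = FALSE)
#' @export
fit_gm <- function(deaths, include_makeham = TRUE) {
  intervals <- collapse_intervals(deaths)
  censored <- censored_of(deaths)
  n_dead <- sum(intervals$n_dead)
  if (nrow(intervals) < 2L)
    stop("all deaths fall in a single interval; GM parameters are not identifiable",
         call. = FALSE)
  if (n_dead < 10L)
    warning("fewer than 10 deaths; GM fit is unreliable", call. = FALSE)

  # Empirical interval hazards for the starting values
  at_risk <- n_dead - cumsum(c(0, intervals$n_dead[-nrow(intervals)]))
  width <- intervals$interval_end - intervals$interval_start
  haz <- intervals$n_dead / pmax(at_risk, 1) / width
  mid <- (intervals$interval_start + intervals$interval_end) / 2
  ok <- haz > 0 & at_risk > 0
  start_ls <- c(-8, 0.05)
  if (sum(ok) >= 2) {
    cf <- coef(lm(log(haz[ok]) ~ mid[ok]))
    start_ls <- c(cf[[1]], max(cf[[2]], 1e-3))
  }
  m_seed <- max(haz[ok][1] / 2, 1e-6)

  starts <- list(c(start_ls[1], log(start_ls[2])),
                 c(-11, log(0.1)), c(-7, log(0.2)), c(-15, log(0.15)))
  if (include_makeham)
    starts <- lapply(starts, function(s) c(s, log(m_seed)))

  negll <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    m <- if (include_makeham) exp(theta[3]) else 0
    ll <- gm_interval_loglik(a, b, m, intervals, censored)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (s in starts) {
    if (!is.finite(negll(s))) next
    o1 <- tryCatch(optim(s, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    o2 <- tryCatch(optim(o1$par, negll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || best$value >= 1e10)
    stop("GM likelihood non-finite at all starting values; check the death table",
         call. = FALSE)
  theta <- best$par
  gm_fit(alpha = exp(theta[1]), beta = exp(theta[2]),
         makeham = if (include_makeham) exp(theta[3]) else 0,
         log_likelihood = -best$value,
         converged = best$convergence == 0, n_obs = n_dead)
}

# Expand an interval-censored table to per-fly event times, using the
# interval end as the event time (deaths are recorded at the census
# following the death).
expand_events <- function(deaths) {
  time <- rep(deaths$interval_end, deaths$n_dead)
  status <- rep(1L, length(time))
  if (!is.null(deaths$n_censored) && any(deaths$n_censored > 0)) {
    time <- c(time, rep(deaths$interval_end, deaths$n_censored))
    status <- c(status, rep(0L, sum(deaths$n_censored)))
  }
  data.frame(time = time, status = status)
}

#' Kaplan--Meier restricted mean lifespan
#'
#' Product-limit estimator on interval-end event times; the restricted
#' mean is the area under the Kaplan--Meier step function up to `tau`
#' (default: the last observed time), with the Greenwood-based standard
#' error, both computed by [survival::survfit()].
#'
#' @param deaths A `death_table`.
#' @param tau Truncation time in days, or `NULL` for the last observed
#'   time.
#' @return A list with `mean` (days) and `se` (days).
#' @export
km_restricted_mean <- function(deaths, tau = NULL) {
  ev <- expand_events(deaths)
  if (nrow(ev) == 0) stop("death table has no events", call. = FALSE)
  if (!is.null(tau) && tau < min(ev$time))
    stop("'tau' precedes the first event time", call. = FALSE)
  fit <- survfit(Surv(time, status) ~ 1, data = ev)
  tab <- summary(fit, rmean = tau %||% max(ev$time))$table
  list(mean = unname(tab[grep("^\\*?rmean$", names(tab))]),
       se = unname(tab[grep("se(rmean)", names(tab), fixed = TRUE)]))
}

#' k-sample log-rank test across death tables
#'
#' Pools interval-end event times from every group and applies the
#' standard log-rank (Mantel--Haenszel) test via [survival::survdiff()].
#' The statistic is invariant to how flies are partitioned into vials
#' within a group.
#'
#' @param groups A list of `death_table`s (>= 2), or a single
#'   `death_table` with multiple genotypes (split on `genotype`).
#' @return A list with `chi2`, `df`, and `p`.
#' @export
log_rank <- function(groups) {
  if (inherits(groups, "death_table"))
    groups <- split(as.data.frame(groups), groups$genotype)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  ev <- do.call(rbind, lapply(seq_along(groups), function(i) {
    e <- expand_events(groups[[i]])
    e$group <- names(groups)[i] %||% as.character(i)
    e
  }))
  if (sum(ev$status) == 0) stop("no events in any group", call. = FALSE)
  sd <- survdiff(Surv(time, status) ~ group, data = ev)
  df <- length(unique(ev$group)) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Per-genotype demographic summary table
#'
#' Computes, for every genotype in a death table, the Kaplan--Meier
#' restricted mean lifespan with its standard error, the
#' Gompertz--Makeham maximum-likelihood parameters, and model-based
#' hazards at reference ages (default days 45 and 60, the mid-life ages
#' at which model-based hazards are reliably estimated).
#'
#' @param deaths A `death_table` covering one or more genotypes.
#' @param include_makeham Passed to [fit_gm()].
#' @param hazard_ages Ages (days) at which to report the fitted hazard.
#' @param tau Truncation time for the restricted mean (`NULL` = last
#'   observed time per genotype).
#' @return A data frame with one row per genotype: `genotype`,
#'   `mean_lifespan`, `mean_lifespan_se`, `ln_alpha`, `beta`, `makeham`,
#'   `loglik`, `converged`, and one `hazard_d<age>` column per reference
#'   age.
#' @export
demography_table <- function(deaths, include_makeham = TRUE,
                             hazard_ages = c(45, 60), tau = NULL) {
  by_g <- split(as.data.frame(deaths), deaths$genotype)
  rows <- lapply(names(by_g), function(g) {
    d <- by_g[[g]]
    class(d) <- c("death_table", "data.frame")
    km <- km_restricted_mean(d, tau = tau)
    fit <- fit_gm(d, include_makeham = include_makeham)
    hz <- vapply(hazard_ages, function(a) gm_hazard(fit, a), numeric(1))
    names(hz) <- sprintf("hazard_d%g", hazard_ages)
    cbind(data.frame(genotype = g, mean_lifespan = km$mean,
                     mean_lifespan_se = km$se, ln_alpha = log(fit$alpha),
                     beta = fit$beta, makeham = fit$makeham,
                     loglik = fit$log_likelihood,
                     converged = fit$converged, stringsAsFactors = FALSE),
          as.data.frame(as.list(hz)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance in mean lifespan explained by the mortality parameters
#'
#' Ordinary least squares of mean lifespan on `ln(alpha)` and `beta`
#' across genotypes, with adjusted R-squared and marginal (type III)
#' F-tests for each parameter.
#'
#' @param summaries A data frame with columns `mean_lifespan`,
#'   `ln_alpha`, `beta` (e.g. from [demography_table()]), >= 5 rows.
#' @return A list with `adj_r2`, `f_alpha`, `p_alpha`, `f_beta`,
#'   `p_beta`, and the fitted `model`.
#' @export
lifespan_variance_model <- function(summaries) {
  if (nrow(summaries) < 5L) stop("need >= 5 genotypes", call. = FALSE)
  if (abs(cor(summaries$ln_alpha, summaries$beta)) > 0.999)
    warning("ln(alpha) and beta are nearly collinear; marginal tests unstable",
            call. = FALSE)
  fit <- lm(mean_lifespan ~ ln_alpha + beta, data = summaries)
  dr <- stats::drop1(fit, scope = ~ ln_alpha + beta, test = "F")
  list(adj_r2 = summary(fit)$adj.r.squared,
       f_alpha = dr["ln_alpha", "F value"], p_alpha = dr["ln_alpha", "Pr(>F)"],
       f_beta = dr["beta", "F value"], p_beta = dr["beta", "Pr(>F)"],
       model = fit)
}

#' Strehler--Mildvan correlation
#'
#' Spearman correlation between `ln(alpha)` and `beta` across genotypes:
#' the classic negative cross-population association between baseline
#' mortality and rate of aging.
#'
#' @param fits A list of [gm_fit()]s, or a data frame with `ln_alpha`
#'   and `beta` columns.
#' @return A list with `rho` and `p`.
#' @export
strehler_mildvan <- function(fits) {
  if (is.data.frame(fits)) {
    la <- fits$ln_alpha; b <- fits$beta
  } else {
    la <- vapply(fits, function(f) log(f$alpha), numeric(1))
    b <- vapply(fits, function(f) f$beta, numeric(1))
  }
  ct <- suppressWarnings(cor.test(la, b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
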