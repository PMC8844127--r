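# Synthetic cohort generation: Gompertz-Makeham death times binned onto a
# fixed observation grid, mirroring a vial-transfer census design in which
# deaths are only known to have occurred between consecutive transfers.

#' Specify a genotype for cohort simulation
#'
#' Bundles the Gompertz--Makeham hazard parameters of one genotype with its
#' cohort design (number of vials, flies per vial).  The hazard at age `x`
#' (days) is `alpha * exp(beta * x) + makeham`: `alpha` is the baseline
#' (age-independent intrinsic) mortality, `beta` the exponential rate of
#' aging, and `makeham` the age-independent extrinsic mortality.
#'
#' @param genotype_id Character label for the genotype.
#' @param alpha Baseline mortality (day^-1), must be > 0.
#' @param beta Rate of aging (day^-1), must be >= 0.
#' @param makeham Age-independent mortality (day^-1), must be >= 0.
#' @param n_vials Number of replicate vials.
#' @param flies_per_vial Flies housed per vial (cohort size is
#'   `n_vials * flies_per_vial`).
#' @return An object of class `"genotype_spec"`.
#' @examples
#' genotype_spec("G01", alpha = exp(-11.5), beta = 0.115)
#' @export
genotype_spec <- function(genotype_id, alpha, beta, makeham = 0,
                          n_vials = 5L, flies_per_vial = 25L) {
  stop_if_not_scalar(alpha, "alpha")
  stop_if_not_scalar(beta, "beta")
  stop_if_not_scalar(makeham, "makeham")
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (makeham < 0) stop("'makeham' must be >= 0", call. = FALSE)
  if (n_vials < 1L || flies_per_vial < 1L)
    stop("cohort design must have at least one vial and one fly", call. = FALSE)
  structure(list(genotype_id = as.character(genotype_id), alpha = alpha,
                 beta = beta, makeham = makeham, n_vials = as.integer(n_vials),
                 flies_per_vial = as.integer(flies_per_vial),
                 n_flies = as.integer(n_vials) * as.integer(flies_per_vial)),
            class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat(sprintf("genotype_spec %s: ln(alpha) = %.3f, beta = %.4f, M = %.4g, %d flies in %d vials\n",
              x$genotype_id, log(x$alpha), x$beta, x$makeham, x$n_flies,
              x$n_vials))
  invisible(x)
}

#' Draw death times from the Gompertz--Makeham law
#'
#' Exact sampling by competing risks: the Gompertz component is drawn by
#' closed-form inversion of its CDF, `T = (1/beta) * log(1 - (beta/alpha) *
#' log(U))`, the Makeham component as an independent exponential with rate
#' `makeham`, and the death time is the minimum of the two -- which has
#' exactly the hazard `alpha * exp(beta * x) + makeham`.
#'
#' @param n Number of death times to draw.
#' @param alpha,beta,makeham Hazard parameters (see [genotype_spec()]).
#' @return Numeric vector of `n` death times in days.
#' @export
rgm <- function(n, alpha, beta, makeham = 0) {
  if (alpha < 0 || beta < 0 || makeham < 0)
    stop("hazard parameters must be non-negative", call. = FALSE)
  if (alpha == 0 && makeham == 0)
    stop("degenerate hazard: alpha and makeham both zero gives no deaths",
         call. = FALSE)
  t_gomp <- if (alpha == 0) {
    rep(Inf, n)
  } else if (beta == 0) {
    rexp(n, rate = alpha)
  } else {
    u <- runif(n)
    log1p(-(beta / alpha) * log(u)) / beta
  }
  t_mak <- if (makeham == 0) rep(Inf, n) else rexp(n, rate = makeham)
  pmin(t_gomp, t_mak)
}

#' Simulate an interval-censored death table for one genotype
#'
#' Draws one Gompertz--Makeham death time per fly (see [rgm()]), assigns
#' flies to vials, and bins deaths into `[k * observe_interval,
#' (k + 1) * observe_interval)` windows, emulating a census at every vial
#' transfer.  Total deaths across intervals always equal the cohort size.
#'
#' @param spec A [genotype_spec()].
#' @param observe_interval Census spacing in days (default 2, every other
#'   day).
#' @param seed Optional integer seed.
#' @return A `death_table` data frame with columns `genotype`, `vial`,
#'   `interval_start`, `interval_end`, `n_dead`.
#' @examples
#' d <- simulate_gm_deaths(genotype_spec("G01", exp(-11.5), 0.115), seed = 1)
#' sum(d$n_dead)  # 125
#' @export
simulate_gm_deaths <- function(spec, observe_interval = 2, seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"))
  stop_if_not_scalar(observe_interval, "observe_interval")
  if (observe_interval <= 0) stop("'observe_interval' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- rgm(spec$n_flies, spec$alpha, spec$beta, spec$makeham)
  vial <- rep(sprintf("V%d", seq_len(spec$n_vials)), each = spec$flies_per_vial)
  k <- floor(times / observe_interval)
  tab <- stats::aggregate(list(n_dead = rep(1L, length(k))),
                          by = list(vial = vial, k = k), FUN = sum)
  out <- data.frame(genotype = spec$genotype_id, vial = tab$vial,
                    interval_start = tab$k * observe_interval,
                    interval_end = (tab$k + 1) * observe_interval,
                    n_dead = tab$n_dead, stringsAsFactors = FALSE)
  out <- out[order(out$vial, out$interval_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("death_table", "data.frame")
  out
}

#' Simulate a multi-genotype cohort with a Strehler--Mildvan structure
#'
#' Draws `(ln alpha, beta)` pairs from a Gaussian copula over uniform
#' margins so that their Spearman correlation matches `sm_coupling` (the
#' negative cross-population association between baseline mortality and
#' rate of aging), then simulates an interval-censored death table for
#' each genotype.  Default parameter ranges are calibrated so that 20
#' genotypes span mean lifespans of roughly 37--82 days.
#'
#' @param n_genotypes Number of genotypes (at least 3).
#' @param ln_alpha_range Range of `ln(alpha)` (day^-1, log scale).
#' @param beta_range Range of `beta` (day^-1).
#' @param sm_coupling Target Spearman correlation between `ln(alpha)` and
#'   `beta`, in `[-1, 0]`.
#' @param makeham_range Range of the age-independent hazard `M`.
#' @param n_vials,flies_per_vial Cohort design per genotype.
#' @param observe_interval Census spacing in days.
#' @param seed Optional integer seed.
#' @return A list with elements `specs` (list of [genotype_spec()]s, with
#'   a `true_mean_lifespan` attribute each) and `deaths` (combined
#'   `death_table` for all genotypes).
#' @export
simulate_population <- function(n_genotypes = 20L,
                                ln_alpha_range = c(-16.5, -7),
                                beta_range = c(0.075, 0.25),
                                sm_coupling = -0.8,
                                makeham_range = c(0, 0.004),
                                n_vials = 5L, flies_per_vial = 25L,
                                observe_interval = 2, seed = NULL) {
  if (n_genotypes < 3L)
    stop("need at least 3 genotypes for cross-genotype correlations",
         call. = FALSE)
  if (abs(sm_coupling) > 1) stop("|sm_coupling| must be <= 1", call. = FALSE)
  if (any(diff(ln_alpha_range) <= 0) || any(diff(beta_range) < 0))
    stop("parameter ranges must be increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # Gaussian copula correlation that yields the requested Spearman rho
  r <- 2 * sin(sm_coupling * pi / 6)
  z1 <- rnorm(n_genotypes)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_genotypes)
  ln_alpha <- ln_alpha_range[1] + pnorm(z1) * diff(ln_alpha_range)
  beta <- beta_range[1] + pnorm(z2) * diff(beta_range)
  makeham <- runif(n_genotypes, makeham_range[1], makeham_range[2])
  ids <- sprintf("G%02d", seq_len(n_genotypes))
  specs <- vector("list", n_genotypes)
  deaths <- vector("list", n_genotypes)
  for (i in seq_len(n_genotypes)) {
    sp <- genotype_spec(ids[i], exp(ln_alpha[i]), beta[i], makeham[i],
                        n_vials = n_vials, flies_per_vial = flies_per_vial)
    attr(sp, "true_mean_lifespan") <-
      gm_mean_lifespan(ln_alpha[i], beta[i], makeham[i])
    specs[[i]] <- sp
    deaths[[i]] <- simulate_gm_deaths(sp, observe_interval = observe_interval)
  }
  all_deaths <- do.call(rbind, deaths)
  class(all_deaths) <- c("death_table", "data.frame")
  list(specs = specs, deaths = all_deaths)
}

#' Expected lifespan under a Gompertz--Makeham hazard
#'
#' Mean lifespan as the integral of the survival function, by adaptive
#' quadrature.
#'
#' @param ln_alpha Log baseline mortality.
#' @param beta Rate of aging (day^-1).
#' @param makeham Age-independent hazard (day^-1).
#' @return Mean lifespan in days.
#' @export
gm_mean_lifespan <- function(ln_alpha, beta, makeham = 0) {
  a <- exp(ln_alpha)
  surv <- function(x) {
    if (beta > 0) exp(-makeham * x - (a / beta) * (exp(beta * x) - 1))
    else exp(-(a + makeham) * x)
  }
  integrate(Vectorize(surv), 0, Inf, rel.tol = 1e-9)$value
}

#' Read / write interval-censored death tables
#'
#' `write_death_table()` stores one row per (genotype, vial, census day)
#' with the number of deaths observed at that census; `read_death_table()`
#' reconstructs the observation intervals `[day - observe_interval, day)`.
#'
#' @param deaths A `death_table` data frame.
#' @param path CSV file path.
#' @param observe_interval Census spacing used when the table was recorded.
#' @return `read_death_table()` returns a `death_table`;
#'   `write_death_table()` returns `path` invisibly.
#' @export
write_death_table <- function(deaths, path) {
  out <- data.frame(genotype = deaths$genotype, vial = deaths$vial,
                    day = deaths$interval_end, n_dead = deaths$n_dead)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_death_table
#' @export
read_death_table <- function(path, observe_interval = 2) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "vial", "day", "n_dead")
  if (!all(need %in% names(x)))
    stop(sprintf("death table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  out <- data.frame(genotype = as.character(x$genotype),
                    vial = as.character(x$vial),
                    interval_start = x$day - observe_interval,
                    interval_end = x$day, n_dead = x$n_dead,
                    stringsAsFactors = FALSE)
  class(out) <- c("death_table", "data.frame")
  out
}
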