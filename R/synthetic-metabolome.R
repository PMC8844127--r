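# Synthetic targeted-metabolome and phenotype generators.  Intensities
# are generated at the "peak area table" level on the log scale and
# exponentiated, so that the preprocessing stage (log + per-sample
# standardization) applies exactly as it would to real peak areas.
# Every planted effect is returned as a ground-truth label.

#' Configuration for the metabolome simulator
#'
#' Proportions of metabolites carrying each effect class default to the
#' observed composition of a real targeted panel: ~33% increasing and
#' ~36% decreasing with age, ~93% with genotype effects, and ~43% with
#' age-by-genotype interactions.  Effect sizes are configuration
#' parameters (real studies report which effects exist, not their
#' sizes); the defaults are calibrated by pilot simulation to give high
#' power at FDR 0.01 under the default replicate design.
#'
#' @param n_metabolites Number of metabolites in the panel.
#' @param ages Sampling ages in days.
#' @param frac_age_increase,frac_age_decrease Proportions of metabolites
#'   rising/falling with age (their sum must be <= 1).
#' @param frac_genotype Proportion with genotype main effects.
#' @param frac_interaction Proportion with age-by-genotype interactions.
#' @param clock_signal_n Number of metabolites carrying a linear age
#'   signal usable by the clock; defaults to all age-trend metabolites
#'   and cannot exceed them (clock members must have monotone trends).
#' @param aa_coupling Effect size linking the late-age metabolome offset
#'   of a genotype to its lifespan deficit: samples of a genotype whose
#'   lifespan is `d` days below the reference are shifted along the
#'   planted clock direction by `aa_coupling * d` days at the two oldest
#'   pre-day-45 ages.  0 disables the coupling.
#' @param aa_ages Ages (days) at which the lifespan coupling acts;
#'   early-age samples carry no lifespan signal.
#' @param age_slope_range Magnitude range of planted per-day age slopes
#'   (log-intensity units per day).
#' @param genotype_sd SD of planted genotype main effects (log units).
#' @param interaction_slope_sd SD of per-genotype deviations from the
#'   common age slope (log units per day).
#' @param noise_sd Residual SD (log units).
#' @param replicate_design Named integer vector mapping genotype id to
#'   biological replicates per age; `NULL` builds the default design
#'   (a quarter of genotypes with 4 replicates, a quarter with 2, the
#'   rest with 1).
#' @param seed Optional integer seed.
#' @return A list of class `"metabolome_sim_config"`.
#' @export
metabolome_sim_config <- function(n_metabolites = 87L,
                                  ages = c(4, 10, 24, 45, 69, 80),
                                  frac_age_increase = 0.333,
                                  frac_age_decrease = 0.356,
                                  frac_genotype = 0.931,
                                  frac_interaction = 0.425,
                                  clock_signal_n = NULL,
                                  aa_coupling = 0.75,
                                  aa_ages = c(24, 45),
                                  age_slope_range = c(0.02, 0.05),
                                  genotype_sd = 0.7,
                                  interaction_slope_sd = 0.05,
                                  noise_sd = 1,
                                  replicate_design = NULL,
                                  seed = NULL) {
  fr <- c(frac_age_increase, frac_age_decrease, frac_genotype,
          frac_interaction)
  if (any(fr < 0 | fr > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (frac_age_increase + frac_age_decrease > 1)
    stop("frac_age_increase + frac_age_decrease must be <= 1", call. = FALSE)
  n_inc <- round(frac_age_increase * n_metabolites)
  n_dec <- round(frac_age_decrease * n_metabolites)
  if (is.null(clock_signal_n)) clock_signal_n <- n_inc + n_dec
  if (clock_signal_n > n_metabolites)
    stop("clock_signal_n must be <= n_metabolites", call. = FALSE)
  if (clock_signal_n > n_inc + n_dec) {
    warning("clock_signal_n capped at the number of age-trend metabolites",
            call. = FALSE)
    clock_signal_n <- n_inc + n_dec
  }
  structure(list(n_metabolites = as.integer(n_metabolites), ages = ages,
                 n_inc = n_inc, n_dec = n_dec,
                 frac_genotype = frac_genotype,
                 frac_interaction = frac_interaction,
                 clock_signal_n = as.integer(clock_signal_n),
                 aa_coupling = aa_coupling, aa_ages = aa_ages,
                 age_slope_range = age_slope_range,
                 genotype_sd = genotype_sd,
                 interaction_slope_sd = interaction_slope_sd,
                 noise_sd = noise_sd, replicate_design = replicate_design,
                 seed = seed),
            class = "metabolome_sim_config")
}

default_replicate_design <- function(ids) {
  n <- length(ids)
  n4 <- max(1L, round(n / 4)); n2 <- max(1L, round(n / 4))
  reps <- c(rep(4L, n4), rep(2L, n2), rep(1L, max(0L, n - n4 - n2)))[seq_len(n)]
  setNames(reps, ids)
}

lifespan_of <- function(spec) {
  attr(spec, "true_mean_lifespan") %||%
    gm_mean_lifespan(log(spec$alpha), spec$beta, spec$makeham)
}

#' Simulate a targeted-metabolome intensity table with truth labels
#'
#' Generates per-sample intensities for a multi-genotype, multi-age
#' design: each metabolite is assigned to effect classes (age increase /
#' decrease / null, genotype, interaction) in the configured
#' proportions; age-trend metabolites carry linear trends and define the
#' planted clock direction; when `aa_coupling != 0`, samples of
#' short-lived genotypes at the late pre-day-45 ages are shifted along
#' that direction in proportion to their lifespan deficit relative to
#' the reference (median) lifespan, so that a clock fitted downstream
#' reads them as biologically older.  Genotypes drop out of ages their
#' cohorts would not survive to (survival below 10%), so late ages are
#' unbalanced as in a real aging study.
#'
#' @param specs List of [genotype_spec()]s (e.g. from
#'   [simulate_population()]).
#' @param config A [metabolome_sim_config()].
#' @param reference_lifespan Reference for the lifespan coupling;
#'   default is the median of the genotype mean lifespans.
#' @return A list with `mat` (a [metabolite_matrix()]) and `truth` (a
#'   list holding the per-metabolite class labels, planted slopes, the
#'   lifespans used, and the configuration).
#' @export
simulate_metabolome <- function(specs, config = metabolome_sim_config(),
                                reference_lifespan = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- vapply(specs, function(s) s$genotype_id, character(1))
  L <- vapply(specs, lifespan_of, numeric(1))
  names(L) <- ids
  ref_L <- reference_lifespan %||% median(L)
  design <- config$replicate_design %||% default_replicate_design(ids)
  if (!all(names(design) %in% ids) || !all(ids %in% names(design)))
    stop("replicate_design must name exactly the simulated genotypes",
         call. = FALSE)

  p <- config$n_metabolites
  met <- sprintf("M%03d", seq_len(p))
  age_class <- rep("none", p)
  if (config$n_inc > 0) age_class[seq_len(config$n_inc)] <- "increase"
  if (config$n_dec > 0)
    age_class[config$n_inc + seq_len(config$n_dec)] <- "decrease"
  slope <- numeric(p)
  trend <- which(age_class != "none")
  slope[trend] <- runif(length(trend), config$age_slope_range[1],
                        config$age_slope_range[2]) *
    ifelse(age_class[trend] == "increase", 1, -1)
  clock_member <- rep(FALSE, p)
  clock_member[trend[seq_len(config$clock_signal_n)]] <- TRUE
  has_geno <- seq_len(p) %in% sample.int(p, round(config$frac_genotype * p))
  has_int <- seq_len(p) %in% sample.int(p, round(config$frac_interaction * p))

  mu <- rnorm(p, mean = 5, sd = 2)
  g_eff <- matrix(0, length(ids), p, dimnames = list(ids, met))
  g_eff[, has_geno] <- rnorm(length(ids) * sum(has_geno), 0, config$genotype_sd)
  d_eff <- matrix(0, length(ids), p, dimnames = list(ids, met))
  d_eff[, has_int] <- rnorm(length(ids) * sum(has_int), 0,
                            config$interaction_slope_sd)
  # Make the interaction deviations orthogonal to the clock direction
  # (within the affected metabolites), so the lifespan coupling below is
  # the only genotype-level displacement along the clock axis.
  cvec <- slope * clock_member
  intc <- which(has_int & clock_member & cvec != 0)
  if (length(intc) > 1L) {
    cc <- cvec[intc]
    proj <- drop(d_eff[, intc, drop = FALSE] %*% cc) / sum(cc^2)
    d_eff[, intc] <- d_eff[, intc, drop = FALSE] - outer(proj, cc)
  }

  early_ages <- head(sort(config$ages), 4)
  x_center <- mean(config$ages)
  # sample table with survival-based late-age dropout
  rows <- list()
  for (i in seq_along(ids)) {
    sp <- specs[[i]]
    for (a in config$ages) {
      present <- a <= max(early_ages) ||
        gm_survival(list(alpha = sp$alpha, beta = sp$beta,
                         makeham = sp$makeham), a) > 0.1
      if (!present) next
      for (r in seq_len(design[[ids[i]]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = ids[i], age_day = a, replicate = r,
          block = if (i <= ceiling(length(ids) * 0.55)) 1L else 2L,
          batch = sprintf("B%d.%d", (i - 1L) %/% 5L + 1L, r),
          stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, rows)
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(samples))),
                        samples, stringsAsFactors = FALSE)

  n <- nrow(samples)
  gi <- match(samples$genotype, ids)
  xc <- samples$age_day - x_center
  aa_on <- samples$age_day %in% config$aa_ages
  shift_days <- ifelse(aa_on, config$aa_coupling * (ref_L - L[gi]), 0)
  vals <- matrix(rnorm(n * p, 0, config$noise_sd), n, p,
                 dimnames = list(samples$sample_id, met))
  vals <- vals + rep(mu, each = n) +
    outer(xc, slope) + g_eff[gi, , drop = FALSE] +
    d_eff[gi, , drop = FALSE] * xc +
    outer(shift_days, slope * clock_member)
  mat <- metabolite_matrix(exp(vals), samples)

  truth <- list(
    metabolites = data.frame(metabolite = met, age_class = age_class,
                             age_slope = slope, genotype_effect = has_geno,
                             interaction_effect = has_int,
                             clock_member = clock_member,
                             stringsAsFactors = FALSE),
    lifespans = data.frame(genotype = ids, true_mean_lifespan = unname(L),
                           stringsAsFactors = FALSE),
    reference_lifespan = ref_L,
    config = unclass(config))
  list(mat = mat, truth = truth)
}

#' Simulate activity and fecundity tables
#'
#' Activity declines linearly over weeks 3--6 with a genotype-specific
#' slope, and its level is positively coupled to lifespan (so that
#' mid-life activity correlates with mean lifespan downstream), while
#' weeks 1--2 carry idiosyncratic non-monotone variation.  Fecundity at
#' the two assay days shares a genotype effect (making the two days
#' correlated with each other) but is generated independently of
#' lifespan.
#'
#' @param specs List of [genotype_spec()]s.
#' @param activity_coupling Activity units gained per day of lifespan
#'   above the population mean (applies to all weeks).
#' @param activity_base Mean activity level (arbitrary assay units).
#' @param slope_mean,slope_sd Distribution of genotype decline slopes
#'   (units per week, negative = decline).
#' @param noise_sd Residual SD of weekly activity means; 0 gives the
#'   deterministic limit in which the fitted week-3--6 slope equals the
#'   planted slope exactly.
#' @param fecundity_days Assay ages in days.
#' @param seed Optional integer seed.
#' @return A list with `activity` (`genotype`, `week`, `activity`) and
#'   `fecundity` (`genotype`, `age_day`, `offspring_per_female_day`).
#' @export
simulate_phenotypes <- function(specs, activity_coupling = 0.15,
                                activity_base = 25, slope_mean = -2,
                                slope_sd = 0.4, noise_sd = 0.5,
                                fecundity_days = c(8, 12), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(specs, function(s) s$genotype_id, character(1))
  L <- vapply(specs, lifespan_of, numeric(1))
  level <- activity_base + activity_coupling * (L - mean(L))
  decline <- rnorm(length(ids), slope_mean, slope_sd)
  act <- list()
  for (i in seq_along(ids)) {
    for (w in 1:6) {
      a <- if (w < 3) {
        level[i] + rnorm(1, 0, 2)          # idiosyncratic early pattern
      } else {
        level[i] + decline[i] * (w - 3) +
          (if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0)
      }
      act[[length(act) + 1L]] <- data.frame(genotype = ids[i], week = w,
                                            activity = a,
                                            stringsAsFactors = FALSE)
    }
  }
  m <- rnorm(length(ids), log(2), 0.35)    # shared genotype fecundity effect
  fec <- list()
  for (i in seq_along(ids)) {
    for (d in fecundity_days) {
      fec[[length(fec) + 1L]] <- data.frame(
        genotype = ids[i], age_day = d,
        offspring_per_female_day = exp(m[i] + rnorm(1, 0, 0.2)),
        stringsAsFactors = FALSE)
    }
  }
  list(activity = do.call(rbind, act), fecundity = do.call(rbind, fec),
       planted = data.frame(genotype = ids, level = level,
                            decline_slope = decline,
                            stringsAsFactors = FALSE))
}
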