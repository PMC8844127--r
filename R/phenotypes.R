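# Age-specific functional phenotypes: fecundity per female-day, the
# week-3-to-6 activity decline, and their nonparametric correlations with
# demographic parameters.

#' Offspring per female per day
#'
#' @param n_offspring Count of viable offspring in a vial.
#' @param n_females_alive Females alive in the vial over the interval.
#' @param interval_days Length of the egg-laying interval in days.
#' @return Offspring per female per day.
#' @examples
#' fecundity_per_female(100, 25, 2)  # 2
#' @export
fecundity_per_female <- function(n_offspring, n_females_alive, interval_days) {
  if (any(n_females_alive <= 0))
    stop("'n_females_alive' must be > 0", call. = FALSE)
  if (any(interval_days <= 0))
    stop("'interval_days' must be > 0", call. = FALSE)
  if (any(n_offspring < 0)) stop("'n_offspring' must be >= 0", call. = FALSE)
  n_offspring / (n_females_alive * interval_days)
}

#' Rate of activity decline over a window of weeks
#'
#' OLS slope of mean activity on week, restricted to `week_range`
#' (default weeks 3--6, the window of monotone decline).
#'
#' @param series Data frame with columns `week` and `activity` for one
#'   genotype, or columns `genotype`, `week`, `activity` for many.
#' @param week_range Inclusive window of weeks.
#' @return For a single genotype, the slope (activity units per week);
#'   for many, a data frame `genotype`, `slope`.
#' @export
activity_decline_slope <- function(series, week_range = c(3, 6)) {
  one <- function(df) {
    df <- df[df$week >= week_range[1] & df$week <= week_range[2], , drop = FALSE]
    if (nrow(df) < 3L)
      stop("need at least 3 weeks inside the window", call. = FALSE)
    unname(coef(lm(activity ~ week, data = df))[2])
  }
  if (!is.null(series$genotype) && length(unique(series$genotype)) > 1L) {
    sl <- vapply(split(series, series$genotype), one, numeric(1))
    data.frame(genotype = names(sl), slope = unname(sl),
               stringsAsFactors = FALSE)
  } else one(series)
}

# Spearman correlation with exact permutation p for small n (no ties)
# and the t-approximation otherwise; ties get average ranks.
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = length(x) < 10 && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlations between phenotypes and demographic parameters
#'
#' Spearman's rho (average ranks for ties) between every age-specific
#' phenotype (weekly activity, activity-decline slope, fecundity at each
#' assay day) and each demographic parameter (mean lifespan,
#' `ln(alpha)`, `beta`) across genotypes.  Constant phenotype vectors
#' yield missing correlations with a warning.
#'
#' @param activity Data frame `genotype`, `week`, `activity`.
#' @param fecundity Data frame `genotype`, `age_day`,
#'   `offspring_per_female_day`.
#' @param summaries Demography table with `genotype`, `mean_lifespan`,
#'   `ln_alpha`, `beta` (see [demography_table()]).
#' @return A long data frame `phenotype`, `parameter`, `rho`, `p`.
#' @export
phenotype_demography_correlations <- function(activity, fecundity, summaries) {
  genos <- sort(unique(summaries$genotype))
  if (length(genos) < 5L) stop("need >= 5 genotypes in common", call. = FALSE)
  phen <- list()
  for (w in sort(unique(activity$week))) {
    v <- activity$activity[match(paste(genos, w),
                                 paste(activity$genotype, activity$week))]
    phen[[sprintf("activity_week%d", w)]] <- v
  }
  sl <- activity_decline_slope(activity)
  phen[["activity_slope_w3_6"]] <- sl$slope[match(genos, sl$genotype)]
  for (a in sort(unique(fecundity$age_day))) {
    v <- fecundity$offspring_per_female_day[
      match(paste(genos, a), paste(fecundity$genotype, fecundity$age_day))]
    phen[[sprintf("fecundity_day%g", a)]] <- v
  }
  pars <- summaries[match(genos, summaries$genotype),
                    c("mean_lifespan", "ln_alpha", "beta")]
  rows <- list()
  for (pn in names(phen)) {
    if (all(is.na(phen[[pn]])) ||
        sd(phen[[pn]], na.rm = TRUE) == 0) {
      warning(sprintf("phenotype '%s' is constant; correlation undefined", pn),
              call. = FALSE)
    }
    for (dn in names(pars)) {
      sc <- spearman_cor(phen[[pn]], pars[[dn]])
      rows[[length(rows) + 1L]] <-
        data.frame(phenotype = pn, parameter = dn, rho = sc$rho, p = sc$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype and age effects on activity
#'
#' Convenience two-way fixed-effects ANOVA of activity on genotype and
#' week (both categorical), matching the factorial screen used for
#' climbing data.
#'
#' @param activity Data frame `genotype`, `week`, `activity`.
#' @return The [stats::anova()] table of the fit.
#' @export
activity_anova <- function(activity) {
  activity$genotype <- factor(activity$genotype)
  activity$week <- factor(activity$week)
  anova(lm(activity ~ genotype + week, data = activity))
}
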