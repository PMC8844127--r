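# Metabolite-matrix container, preprocessing (log + per-sample
# standardization with a QC drop rule), per-metabolite age-by-genotype
# linear models with BH-FDR, PCA, and metabolite-demography association
# screens.

#' Metabolite matrix with sample metadata
#'
#' @param values Numeric sample-by-metabolite matrix (no missing
#'   values); rows are samples.
#' @param samples Data frame with one row per sample: `sample_id`,
#'   `genotype`, `age_day`, `replicate`, `block`, `batch`.
#' @param normalized Has the matrix been through [preprocess()]?
#' @return An object of class `"metabolite_matrix"`.
#' @export
metabolite_matrix <- function(values, samples, normalized = FALSE) {
  values <- as.matrix(values)
  need <- c("sample_id", "genotype", "age_day")
  if (!all(need %in% names(samples)))
    stop(sprintf("sample metadata must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(values) != nrow(samples))
    stop("values and samples disagree on the number of samples", call. = FALSE)
  if (anyNA(values)) stop("metabolite matrix has missing values", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  structure(list(values = values, samples = as.data.frame(samples),
                 normalized = isTRUE(normalized)),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d samples x %d metabolites (%s), %d genotypes, ages %s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw intensities",
              length(unique(x$samples$genotype)),
              paste(sort(unique(x$samples$age_day)), collapse = "/")))
  invisible(x)
}

#' @rdname metabolite_matrix
#' @param mat A `metabolite_matrix`.
#' @param path CSV path; the layout is one row per sample with metadata
#'   columns followed by one column per metabolite.
#' @export
write_metabolite_matrix <- function(mat, path) {
  out <- cbind(mat$samples, as.data.frame(mat$values))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname metabolite_matrix
#' @export
read_metabolite_matrix <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "genotype", "age_day", "replicate",
                           "block", "batch"), names(x))
  met_cols <- setdiff(names(x), meta_cols)
  metabolite_matrix(as.matrix(x[, met_cols, drop = FALSE]),
                    x[, meta_cols, drop = FALSE])
}

#' Log-transform, QC-screen, and per-sample standardize intensities
#'
#' Intensities are natural-log transformed, then screened: a sample is
#' dropped (with a logged reason) when the fraction of its metabolites
#' with robust z-scores (median/MAD across samples, per metabolite)
#' exceeding 4 in absolute value is above `qc_threshold` -- the rule a
#' analyst would apply to a replicate in which a third of the panel is
#' visibly abnormal.  Surviving samples are centred and scaled so every
#' sample row has mean 0 and SD 1 across metabolites.
#'
#' @param raw A [metabolite_matrix()] of positive raw intensities.
#' @param qc_threshold Maximum tolerated fraction of outlying
#'   metabolites per sample (default 1/3).
#' @param log_transform Apply the log first?  Set `FALSE` when the
#'   matrix is already on the log scale.
#' @return A normalized [metabolite_matrix()].
#' @export
preprocess <- function(raw, qc_threshold = 1/3, log_transform = TRUE) {
  v <- raw$values
  if (log_transform) {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-positive intensity at sample '%s', metabolite '%s'",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
           call. = FALSE)
    v <- log(v)
  }
  med <- apply(v, 2, median)
  madv <- apply(v, 2, mad)
  madv[madv == 0] <- Inf   # constant metabolite cannot flag outliers
  z <- sweep(sweep(v, 2, med), 2, madv, "/")
  frac_out <- rowMeans(abs(z) > 4)
  drop <- frac_out > qc_threshold
  if (any(drop)) {
    message(sprintf("preprocess: dropping %d sample(s) with > %.0f%% outlying metabolites: %s",
                    sum(drop), 100 * qc_threshold,
                    paste(rownames(v)[drop], collapse = ", ")))
    v <- v[!drop, , drop = FALSE]
  }
  v <- t(scale(t(v)))   # per-sample centre and scale across metabolites
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  if (anyNA(v)) stop("a sample is constant across metabolites; cannot scale",
                     call. = FALSE)
  metabolite_matrix(v, raw$samples[!drop, , drop = FALSE], normalized = TRUE)
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, in `[0, 1]`).
#'
#' @param pvalues Numeric vector of p-values (NAs preserved).
#' @return Adjusted q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvalues) p.adjust(pvalues, method = "BH")

# Ages at which most genotypes are present (the balanced early design).
balanced_ages <- function(mat, n = 4) head(sort(unique(mat$samples$age_day)), n)

#' Per-metabolite age-by-genotype linear models
#'
#' Fits, for every metabolite, the fixed-effects model `level ~ Age +
#' Genotype + Age:Genotype` with age categorical, and reports the ANOVA
#' F-test p-value of each term with Benjamini--Hochberg q-values
#' adjusted within each term family across metabolites.  By default the
#' model is restricted to the early, near-balanced ages (the first four
#' sampling ages), because late-age genotype dropout makes the full
#' design unbalanced.  For metabolites significant for age at the FDR
#' threshold, the direction label is the sign of the OLS slope of level
#' on numeric age.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @param fdr FDR threshold used for the direction labels (default 0.01).
#' @param ages Ages to include; default the first four sampling ages.
#' @return A data frame with one row per metabolite: `metabolite`,
#'   `p_age`, `p_genotype`, `p_interaction`, matching `q_` columns, and
#'   `age_direction` (`"increase"`, `"decrease"`, `"none"`).
#' @export
fit_age_genotype_model <- function(mat, fdr = 0.01, ages = NULL) {
  ages <- ages %||% balanced_ages(mat)
  keep <- mat$samples$age_day %in% ages
  v <- mat$values[keep, , drop = FALSE]
  s <- mat$samples[keep, , drop = FALSE]
  if (length(unique(s$genotype)) < 2L || length(unique(s$age_day)) < 2L)
    stop("need >= 2 genotypes and >= 2 ages", call. = FALSE)
  fage <- factor(s$age_day)
  fgen <- factor(s$genotype)
  n_cells <- length(levels(fage)) * length(levels(fgen))
  if (nrow(v) - n_cells < 1L)
    warning("no residual degrees of freedom for the interaction model",
            call. = FALSE)
  age_num <- s$age_day
  res <- lapply(seq_len(ncol(v)), function(j) {
    y <- v[, j]
    a <- anova(lm(y ~ fage * fgen))
    slope <- coef(lm(y ~ age_num))[2]
    data.frame(metabolite = colnames(v)[j],
               p_age = a["fage", "Pr(>F)"],
               p_genotype = a["fgen", "Pr(>F)"],
               p_interaction = a["fage:fgen", "Pr(>F)"],
               slope_age = unname(slope), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$p_interaction))
    warning("interaction inestimable for some metabolites (empty cells)",
            call. = FALSE)
  out$q_age <- bh_fdr(out$p_age)
  out$q_genotype <- bh_fdr(out$p_genotype)
  out$q_interaction <- bh_fdr(out$p_interaction)
  out$age_direction <- ifelse(!is.na(out$q_age) & out$q_age < fdr,
                              ifelse(out$slope_age > 0, "increase", "decrease"),
                              "none")
  rownames(out) <- NULL
  out
}

#' Principal component overview of the metabolome
#'
#' Column-centred PCA of the normalized matrix, with PC1 oriented so
#' that its correlation with sample age is non-negative.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @return A list with `scores` (samples x PCs), `loadings`
#'   (metabolites x PCs), `variance_explained` (per-PC variances,
#'   summing to the total variance), and `center`.
#' @export
pca_overview <- function(mat) {
  if (nrow(mat$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  pr <- stats::prcomp(mat$values, center = TRUE, scale. = FALSE)
  flip <- cor(pr$x[, 1], mat$samples$age_day)
  if (!is.na(flip) && flip < 0) {
    pr$x[, 1] <- -pr$x[, 1]
    pr$rotation[, 1] <- -pr$rotation[, 1]
  }
  list(scores = pr$x, loadings = pr$rotation,
       variance_explained = pr$sdev^2, center = pr$center)
}

#' PC1 against age across lifespan groups
#'
#' Categorizes genotypes into short- / medium- / long-lived groups at
#' the given mean-lifespan cutpoints (default < 50 d, 50--65 d, > 65 d)
#' and fits the fixed-effects model `PC1 ~ age + group + age:group`
#' with age numeric, testing whether the age trajectory of the leading
#' metabolome axis differs among lifespan groups.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @param demography Demography table with `genotype` and
#'   `mean_lifespan`.
#' @param cutpoints Two increasing lifespan cutpoints in days.
#' @return The ANOVA table of the fit (terms `age`, `group`,
#'   `age:group`).
#' @export
pc1_lifespan_group_model <- function(mat, demography, cutpoints = c(50, 65)) {
  if (diff(cutpoints) <= 0) stop("cutpoints must be increasing", call. = FALSE)
  pca <- pca_overview(mat)
  ls <- demography$mean_lifespan[match(mat$samples$genotype,
                                       demography$genotype)]
  if (anyNA(ls)) stop("demography table is missing genotypes present in the metabolome",
                      call. = FALSE)
  group <- cut(ls, breaks = c(-Inf, cutpoints, Inf),
               labels = c("short", "medium", "long"))
  group <- droplevels(group)
  if (nlevels(group) < 2L)
    stop("all genotypes fall in a single lifespan group", call. = FALSE)
  if (nlevels(group) < 3L)
    warning("a lifespan group is empty; testing the available groups",
            call. = FALSE)
  df <- data.frame(pc1 = pca$scores[, 1], age = mat$samples$age_day,
                   group = group)
  anova(lm(pc1 ~ age * group, data = df))
}

# Shared engine for the metabolite-demography association screens:
# regress a genotype-level metabolite summary on each demographic
# parameter, with BH adjustment within each (parameter, predictor)
# family, and a Spearman correlation alongside the linear-model test.
assoc_engine <- function(levels_by_genotype, demography, predictor_label,
                         fdr) {
  genos <- rownames(levels_by_genotype)
  idx <- match(genos, demography$genotype)
  if (anyNA(idx)) stop("demography table is missing genotypes", call. = FALSE)
  if (length(genos) < 5L) stop("need >= 5 genotypes", call. = FALSE)
  pars <- c("mean_lifespan", "ln_alpha", "beta")
  rows <- list()
  for (par in pars) {
    phi <- demography[[par]][idx]
    est <- p <- rho <- rep(NA_real_, ncol(levels_by_genotype))
    for (j in seq_len(ncol(levels_by_genotype))) {
      y <- levels_by_genotype[, j]
      if (sd(y, na.rm = TRUE) == 0 || sum(complete.cases(y, phi)) < 3) {
        warning(sprintf("'%s' is constant or too sparse; association skipped",
                        colnames(levels_by_genotype)[j]), call. = FALSE)
        next
      }
      sm <- summary(lm(y ~ phi))
      est[j] <- sm$coefficients["phi", "Estimate"]
      p[j] <- sm$coefficients["phi", "Pr(>|t|)"]
      rho[j] <- spearman_cor(y, phi)$rho
    }
    rows[[par]] <- data.frame(metabolite = colnames(levels_by_genotype),
                              predictor = predictor_label, parameter = par,
                              estimate = est, rho = rho, p = p,
                              q = bh_fdr(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$q) & out$q < fdr
  rownames(out) <- NULL
  out
}

#' Age-specific metabolite levels versus demographic parameters
#'
#' For every metabolite, regresses its genotype-mean level at the given
#' age (replicates averaged -- demographic parameters are genotype-level
#' quantities) on each demographic parameter (mean lifespan,
#' `ln(alpha)`, `beta`), reporting the slope, a Spearman rho, the
#' linear-model p-value, and BH q-values adjusted within each
#' (parameter, age) family.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @param demography Demography table with `genotype`, `mean_lifespan`,
#'   `ln_alpha`, `beta`.
#' @param age Sampling age (days) at which to take levels.
#' @param fdr Significance threshold on the q-value (default 0.2).
#' @return A data frame of association results.
#' @export
level_demography_assoc <- function(mat, demography, age, fdr = 0.2) {
  keep <- mat$samples$age_day == age
  if (!any(keep)) stop(sprintf("no samples at age %g", age), call. = FALSE)
  v <- mat$values[keep, , drop = FALSE]
  g <- mat$samples$genotype[keep]
  means <- apply(v, 2, function(col) tapply(col, g, mean))
  assoc_engine(means, demography, sprintf("level@day%g", age), fdr)
}

#' Per-genotype age trajectories of metabolite levels
#'
#' OLS slope of level on age in days for each (metabolite, genotype)
#' pair, restricted to the early sampling ages (default the first
#' four), where the design is near-balanced.  Genotypes with fewer than
#' 3 ages available are skipped with a warning.
#'
#' @param mat A normalized [metabolite_matrix()].
#' @param ages Ages used; default the first four sampling ages.
#' @return A data frame `metabolite`, `genotype`, `slope` (normalized
#'   units per day).
#' @export
trajectory_slopes <- function(mat, ages = NULL) {
  ages <- ages %||% balanced_ages(mat)
  keep <- mat$samples$age_day %in% ages
  v <- mat$values[keep, , drop = FALSE]
  s <- mat$samples[keep, , drop = FALSE]
  rows <- list()
  for (g in unique(s$genotype)) {
    sel <- s$genotype == g
    if (length(unique(s$age_day[sel])) < 3L) {
      warning(sprintf("genotype '%s' has < 3 ages; trajectory skipped", g),
              call. = FALSE)
      next
    }
    x <- s$age_day[sel] - mean(s$age_day[sel])
    sl <- crossprod(x, v[sel, , drop = FALSE]) / sum(x^2)
    rows[[g]] <- data.frame(metabolite = colnames(v), genotype = g,
                            slope = as.numeric(sl), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metabolite age trajectories versus demographic parameters
#'
#' As [level_demography_assoc()], but the genotype-level predictor is
#' the age-trajectory slope of each metabolite (see
#' [trajectory_slopes()]).
#'
#' @param slopes Output of [trajectory_slopes()].
#' @param demography Demography table.
#' @param fdr Significance threshold on the q-value (default 0.2).
#' @return A data frame of association results.
#' @export
trajectory_demography_assoc <- function(slopes, demography, fdr = 0.2) {
  wide <- stats::reshape(slopes, idvar = "genotype", timevar = "metabolite",
                         direction = "wide")
  rownames(wide) <- wide$genotype
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^slope\\.", "", colnames(m))
  assoc_engine(m, demography, "trajectory", fdr)
}
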