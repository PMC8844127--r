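# End-to-end orchestration: simulate (optional) -> demography ->
# phenotypes -> metabolome screens -> clock, with schema validation, a
# deterministic seed, stage logging, and a run manifest.

#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()], with defaults
#' matching the standard study design: FDR 0.01 for the age-by-genotype
#' screen, FDR 0.2 for the demography-association screens, lifespan
#' group cutpoints at 50 and 65 days, and the default synthetic-cohort
#' and clock settings.
#'
#' @param out_dir Directory for all output tables.
#' @param seed Integer seed governing every stochastic stage.
#' @param simulate Generate synthetic inputs?  If `FALSE`, `deaths`,
#'   `metabolome`, `activity` and `fecundity` must point to existing CSV
#'   files (as written by the simulate stage).
#' @param deaths,metabolome,activity,fecundity Input CSV paths when
#'   `simulate = FALSE`.
#' @param qc_threshold Sample QC threshold for [preprocess()].
#' @param fdr_anova FDR threshold for the age-by-genotype screen.
#' @param fdr_assoc FDR threshold for the association screens.
#' @param cutpoints Lifespan group cutpoints in days (increasing).
#' @param aa_age Age at which age acceleration is tested against
#'   demography.
#' @param n_genotypes,sm_coupling Synthetic-cohort settings (see
#'   [simulate_population()]).
#' @param metabolome_config A [metabolome_sim_config()] (seed is
#'   derived from `seed`).
#' @param clock A [clock_hyperparams()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "metaboclock-out", seed = 1L,
                            simulate = TRUE, deaths = NULL,
                            metabolome = NULL, activity = NULL,
                            fecundity = NULL, qc_threshold = 1/3,
                            fdr_anova = 0.01, fdr_assoc = 0.2,
                            cutpoints = c(50, 65), aa_age = 45,
                            n_genotypes = 20L, sm_coupling = -0.8,
                            metabolome_config = metabolome_sim_config(),
                            clock = clock_hyperparams()) {
  if (fdr_anova <= 0 || fdr_anova >= 1 || fdr_assoc <= 0 || fdr_assoc >= 1)
    stop("FDR thresholds must lie in (0, 1)", call. = FALSE)
  if (diff(cutpoints) <= 0) stop("cutpoints must be increasing", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate), deaths = deaths,
                 metabolome = metabolome, activity = activity,
                 fecundity = fecundity, qc_threshold = qc_threshold,
                 fdr_anova = fdr_anova, fdr_assoc = fdr_assoc,
                 cutpoints = cutpoints, aa_age = aa_age,
                 n_genotypes = as.integer(n_genotypes),
                 sm_coupling = sm_coupling,
                 metabolome_config = metabolome_config, clock = clock),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `metabolome:` and `clock:` blocks mirror [metabolome_sim_config()]
#' and [clock_hyperparams()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  met <- do.call(metabolome_sim_config, y$metabolome %||% list())
  clk <- do.call(clock_hyperparams, y$clock %||% list())
  y$metabolome <- NULL
  y$clock <- NULL
  args <- c(y, list(metabolome_config = met, clock = clk))
  do.call(pipeline_config, args)
}

#' Validate pipeline input tables
#'
#' Checks column presence, positivity of raw intensities, membership of
#' sampling ages in the declared set, and genotype-key consistency
#' across tables.  Problems are returned as a data frame; fatal schema
#' violations carry `severity = "error"`.
#'
#' @param paths Named list with any of `deaths`, `metabolome`,
#'   `activity`, `fecundity`.
#' @param ages Declared metabolome sampling ages.
#' @return A data frame `file`, `severity`, `message` (zero rows when
#'   everything passes), with attribute `ok`.
#' @export
validate_tables <- function(paths, ages = c(4, 10, 24, 45, 69, 80)) {
  issues <- list()
  add <- function(file, severity, msg)
    issues[[length(issues) + 1L]] <<- data.frame(file = file,
                                                 severity = severity,
                                                 message = msg,
                                                 stringsAsFactors = FALSE)
  need <- list(deaths = c("genotype", "vial", "day", "n_dead"),
               metabolome = c("sample_id", "genotype", "age_day"),
               activity = c("genotype", "week", "activity"),
               fecundity = c("genotype", "age_day",
                             "offspring_per_female_day"))
  tabs <- list()
  for (nm in names(need)) {
    p <- paths[[nm]]
    if (is.null(p)) next
    if (!file.exists(p)) {
      add(p, "error", sprintf("%s file not found", nm))
      next
    }
    x <- read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(need[[nm]], names(x))
    if (length(missing) > 0) {
      add(p, "error", sprintf("missing column(s): %s",
                              paste(missing, collapse = ", ")))
      next
    }
    tabs[[nm]] <- x
  }
  if (!is.null(tabs$metabolome)) {
    met_cols <- setdiff(names(tabs$metabolome),
                        c("sample_id", "genotype", "age_day", "replicate",
                          "block", "batch"))
    vals <- as.matrix(tabs$metabolome[, met_cols, drop = FALSE])
    bad <- which(vals <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      add(paths$metabolome, "error",
          sprintf("non-positive intensity at sample '%s', metabolite '%s'",
                  tabs$metabolome$sample_id[bad[1, 1]], met_cols[bad[1, 2]]))
    off <- setdiff(unique(tabs$metabolome$age_day), ages)
    if (length(off) > 0)
      add(paths$metabolome, "error",
          sprintf("age(s) outside the declared sampling set: %s",
                  paste(off, collapse = ", ")))
  }
  if (!is.null(tabs$deaths)) {
    if (any(tabs$deaths$n_dead < 0))
      add(paths$deaths, "error", "negative death counts")
    for (nm in c("metabolome", "activity", "fecundity")) {
      if (is.null(tabs[[nm]])) next
      orphan <- setdiff(unique(tabs[[nm]]$genotype),
                        unique(tabs$deaths$genotype))
      if (length(orphan) > 0)
        add(paths[[nm]], "warning",
            sprintf("genotype(s) absent from the death table: %s",
                    paste(orphan, collapse = ", ")))
    }
  }
  out <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(file = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  attr(out, "ok") <- !any(out$severity == "error")
  out
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[metaboclock] %s %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), demography, phenotypes, the metabolome
#' screens, and the clock, writing every output table under
#' `config$out_dir`: `deaths.csv`, `metabolome.csv`, `activity.csv`,
#' `fecundity.csv`, `truth.json` (simulate stage); `demography.csv`;
#' `phenotype_correlations.csv`; `anova_table1.csv`, `assoc_table2.csv`,
#' `pca_scores.csv`; `clock_eval.csv`, `age_acceleration.csv`,
#' `aa_assoc.csv`; and a `manifest.json` recording the config hash,
#' seed, and package version.  The run is deterministic given the seed.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param quiet Suppress stage logging?
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  set.seed(config$seed)

  if (config$simulate) {
    log_stage(quiet, "simulate: %d genotypes", config$n_genotypes)
    pop <- simulate_population(n_genotypes = config$n_genotypes,
                               sm_coupling = config$sm_coupling)
    sim <- simulate_metabolome(pop$specs, config$metabolome_config)
    phen <- simulate_phenotypes(pop$specs)
    write_death_table(pop$deaths, out("deaths.csv"))
    write_metabolite_matrix(sim$mat, out("metabolome.csv"))
    write.csv(phen$activity, out("activity.csv"), row.names = FALSE)
    write.csv(phen$fecundity, out("fecundity.csv"), row.names = FALSE)
    jsonlite::write_json(sim$truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    deaths <- pop$deaths
    raw <- sim$mat
    activity <- phen$activity
    fecundity <- phen$fecundity
  } else {
    paths <- list(deaths = config$deaths, metabolome = config$metabolome,
                  activity = config$activity, fecundity = config$fecundity)
    rep_ <- validate_tables(paths, ages = config$metabolome_config$ages)
    if (!attr(rep_, "ok"))
      stop(paste(c("input validation failed:",
                   sprintf("  %s: %s", rep_$file, rep_$message)),
                 collapse = "\n"), call. = FALSE)
    deaths <- read_death_table(config$deaths)
    raw <- read_metabolite_matrix(config$metabolome)
    activity <- read.csv(config$activity, stringsAsFactors = FALSE)
    fecundity <- read.csv(config$fecundity, stringsAsFactors = FALSE)
  }

  log_stage(quiet, "demography: GM fits and restricted means")
  demog <- demography_table(deaths)
  write.csv(demog, out("demography.csv"), row.names = FALSE)

  log_stage(quiet, "phenotypes: correlations with demography")
  phen_cor <- phenotype_demography_correlations(activity, fecundity, demog)
  write.csv(phen_cor, out("phenotype_correlations.csv"), row.names = FALSE)

  log_stage(quiet, "metabolome: preprocessing and linear models")
  norm <- preprocess(raw, qc_threshold = config$qc_threshold)
  anova_tab <- fit_age_genotype_model(norm, fdr = config$fdr_anova)
  write.csv(anova_tab, out("anova_table1.csv"), row.names = FALSE)
  assoc <- do.call(rbind, c(
    lapply(balanced_ages(norm), function(a)
      level_demography_assoc(norm, demog, a, fdr = config$fdr_assoc)),
    list(trajectory_demography_assoc(trajectory_slopes(norm), demog,
                                     fdr = config$fdr_assoc))))
  write.csv(assoc, out("assoc_table2.csv"), row.names = FALSE)
  pca <- pca_overview(norm)
  write.csv(cbind(norm$samples[, c("sample_id", "genotype", "age_day")],
                  as.data.frame(pca$scores[, seq_len(min(5, ncol(pca$scores)))])),
            out("pca_scores.csv"), row.names = FALSE)
  pc1_tab <- pc1_lifespan_group_model(norm, demog, config$cutpoints)

  log_stage(quiet, "clock: tuning over %d x %d grid, %d repeats",
            length(config$clock$lambda1_grid),
            length(config$clock$lambda2_grid), config$clock$n_repeats)
  clk_hp <- config$clock
  if (is.null(clk_hp$seed)) clk_hp$seed <- config$seed + 1L
  tuned <- tune_and_evaluate(norm, clk_hp)
  write.csv(tuned$results, out("clock_eval.csv"), row.names = FALSE)
  preds <- loocv_predict(norm, tuned$consensus$lambda1,
                         tuned$consensus$lambda2)
  aa <- age_acceleration(preds)
  write.csv(aa, out("age_acceleration.csv"), row.names = FALSE)
  aa_assoc <- aa_demography_assoc(aa, demog, at_age = config$aa_age)
  write.csv(aa_assoc, out("aa_assoc.csv"), row.names = FALSE)

  manifest <- list(package = "metaboclock",
                   version = as.character(utils::packageVersion("metaboclock")),
                   seed = config$seed, config_hash = config_hash(config),
                   tables = list.files(config$out_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  log_stage(quiet, "done: outputs in %s", config$out_dir)

  invisible(list(demography = demog, phenotype_correlations = phen_cor,
                 anova = anova_tab, associations = assoc, pca = pca,
                 pc1_model = pc1_tab, clock = tuned,
                 age_acceleration = aa, aa_assoc = aa_assoc))
}
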