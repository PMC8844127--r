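# Preprocessing, BH-FDR, the per-metabolite age-by-genotype models, PCA,
# and the metabolite-demography association screens.

test_that("preprocessing yields standardized rows and is idempotent", {
  set.seed(53)
  raw <- tiny_matrix(exp(matrix(rnorm(8 * 20, 5), 8, 20)),
                     genotype = rep(c("A", "B"), each = 4),
                     age_day = rep(c(4, 10), 4), normalized = FALSE)
  norm <- preprocess(raw)
  expect_equal(unname(rowMeans(norm$values)), rep(0, 8), tolerance = 1e-8)
  expect_equal(unname(apply(norm$values, 1, sd)), rep(1, 8), tolerance = 1e-8)
  again <- preprocess(norm, log_transform = FALSE)
  expect_equal(again$values, norm$values, tolerance = 1e-12)
})

test_that("proportional samples normalize identically and bad cells are named", {
  v <- matrix(rexp(2 * 15, 1 / 100), 2, 15)
  v[2, ] <- 2 * v[1, ]
  raw <- tiny_matrix(v, genotype = "A", age_day = c(4, 4), normalized = FALSE)
  norm <- preprocess(raw)
  expect_equal(norm$values[1, ], norm$values[2, ], tolerance = 1e-12)

  v2 <- v; v2[1, 3] <- -1
  raw2 <- tiny_matrix(v2, genotype = "A", age_day = c(4, 4), normalized = FALSE)
  expect_error(preprocess(raw2), "S01.*M003")
})

test_that("samples with a large outlying fraction are dropped", {
  set.seed(59)
  n <- 12; p <- 30
  v <- matrix(rnorm(n * p, 6, 0.3), n, p)
  v[4, 1:12] <- v[4, 1:12] + 10   # 40% of metabolites wildly shifted
  raw <- tiny_matrix(exp(v), genotype = rep(c("A", "B", "C"), each = 4),
                     age_day = rep(c(4, 10, 24, 45), 3), normalized = FALSE)
  expect_message(norm <- preprocess(raw, qc_threshold = 1/3), "dropping 1")
  expect_equal(nrow(norm$values), n - 1)
  expect_false("S04" %in% norm$samples$sample_id)
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("age-by-genotype F-tests match a nested residual-sum-of-squares oracle", {
  set.seed(67)
  # balanced 2 genotypes x 2 ages x 2 replicates
  geno <- rep(c("A", "B"), each = 4)
  age <- rep(c(4, 24, 4, 24), each = 2)
  y <- rnorm(8)
  mat <- tiny_matrix(cbind(m1 = y), genotype = geno, age_day = age)
  res <- fit_age_genotype_model(mat, ages = c(4, 24))
  rss <- function(form) sum(resid(lm(form, data = data.frame(
    y = y, a = factor(age), g = factor(geno))))^2)
  rss0 <- rss(y ~ 1); rss_a <- rss(y ~ a); rss_ag <- rss(y ~ a + g)
  rss_full <- rss(y ~ a * g)
  f_age <- (rss0 - rss_a) / 1 / (rss_full / 4)
  f_gen <- (rss_a - rss_ag) / 1 / (rss_full / 4)
  f_int <- (rss_ag - rss_full) / 1 / (rss_full / 4)
  expect_equal(res$p_age, pf(f_age, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p_genotype, pf(f_gen, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p_interaction, pf(f_int, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("an exact linear age effect is detected with correct direction", {
  geno <- rep(c("A", "B", "C"), each = 8)
  age <- rep(rep(c(4, 10, 24, 45), each = 2), 3)
  up <- 0.1 * age
  down <- -0.05 * age
  mat <- tiny_matrix(cbind(m_up = up, m_down = down),
                     genotype = geno, age_day = age)
  res <- suppressWarnings(fit_age_genotype_model(mat))
  expect_lt(res$p_age[1], 1e-12)
  expect_equal(res$age_direction, c("increase", "decrease"))
})

test_that("inestimable interactions warn and propagate missing values", {
  geno <- c("A", "A", "A", "B", "B")
  age <- c(4, 10, 24, 4, 4)   # genotype B observed at one age only
  mat <- tiny_matrix(cbind(m1 = rnorm(5)), genotype = geno, age_day = age)
  w <- capture_warnings(res <- fit_age_genotype_model(mat, ages = c(4, 10, 24)))
  expect_true(any(grepl("inestimable", w)))
  expect_true(is.na(res$p_interaction))
})

test_that("PCA reconstructs the data and orders its variances", {
  set.seed(71)
  mat <- tiny_matrix(matrix(rnorm(10 * 6), 10, 6),
                     genotype = rep(c("A", "B"), 5),
                     age_day = rep(c(4, 10), each = 5))
  pca <- pca_overview(mat)
  rec <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, 10, 6, byrow = TRUE)
  expect_equal(unname(rec), unname(mat$values), tolerance = 1e-8)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  expect_equal(sum(pca$variance_explained),
               sum(apply(mat$values, 2, var)), tolerance = 1e-8)
})

test_that("PC1 tracks a planted age axis and not permuted labels", {
  pop <- simulate_population(n_genotypes = 10, seed = 73)
  sim <- simulate_metabolome(pop$specs, metabolome_sim_config(seed = 74))
  norm <- preprocess(sim$mat)
  pca <- pca_overview(norm)
  r <- cor(pca$scores[, 1], norm$samples$age_day)
  expect_gt(r, 0.8)   # sign-oriented by construction
  set.seed(75)
  perm <- norm
  perm$samples$age_day <- sample(perm$samples$age_day)
  pcp <- pca_overview(perm)
  expect_lt(abs(cor(pcp$scores[, 1], perm$samples$age_day)), 0.3)
})

test_that("lifespan-group trajectories separate when coupling is planted", {
  pop <- simulate_population(seed = 77)
  sim <- simulate_metabolome(pop$specs, metabolome_sim_config(seed = 78))
  norm <- preprocess(sim$mat)
  demog <- sim$truth$lifespans
  names(demog)[2] <- "mean_lifespan"
  tab <- pc1_lifespan_group_model(norm, demog)
  expect_lt(tab["age", "Pr(>F)"], 1e-10)
  expect_lt(tab["age:group", "Pr(>F)"], 0.01)
  # identical trajectories: group terms vanish
  geno <- rep(c("A", "B", "C", "D", "E", "F"), each = 4)
  age <- rep(c(4, 10, 24, 45), 6)
  flat <- tiny_matrix(cbind(m1 = 0.1 * age, m2 = -0.1 * age + rnorm(24, 0, 1e-8)),
                      genotype = geno, age_day = age)
  dem2 <- data.frame(genotype = c("A", "B", "C", "D", "E", "F"),
                     mean_lifespan = c(40, 45, 55, 60, 70, 80))
  tab2 <- suppressWarnings(pc1_lifespan_group_model(flat, dem2))
  expect_gt(tab2["group", "Pr(>F)"], 0.05)
  dem3 <- dem2; dem3$mean_lifespan <- rep(40, 6)
  expect_error(pc1_lifespan_group_model(flat, dem3), "single lifespan group")
})

test_that("level and trajectory screens recover planted lifespan coupling", {
  set.seed(79)
  genos <- sprintf("G%02d", 1:12)
  L <- seq(40, 80, length.out = 12)
  demog <- data.frame(genotype = genos, mean_lifespan = L,
                      ln_alpha = rnorm(12, -12, 1), beta = runif(12, 0.1, 0.2))
  ages <- c(4, 10, 24, 45)
  s <- expand.grid(genotype = genos, age_day = ages,
                   stringsAsFactors = FALSE)
  p <- 20
  v <- matrix(rnorm(nrow(s) * p), nrow(s), p,
              dimnames = list(NULL, sprintf("M%03d", 1:p)))
  # metabolite 1: level at day 45 proportional to lifespan
  sel <- s$age_day == 45
  v[sel, 1] <- 0.1 * L[match(s$genotype[sel], genos)] + rnorm(sum(sel), 0, 0.2)
  # metabolite 2: age slope proportional to lifespan
  v[, 2] <- 0.002 * L[match(s$genotype, genos)] * s$age_day +
    rnorm(nrow(s), 0, 0.1)
  mat <- tiny_matrix(v, genotype = s$genotype, age_day = s$age_day)
  lv <- level_demography_assoc(mat, demog, age = 45)
  hit <- lv[lv$metabolite == "M001" & lv$parameter == "mean_lifespan", ]
  expect_lt(hit$q, 0.2)
  expect_gt(hit$estimate, 0)
  null_q <- lv$q[lv$parameter == "mean_lifespan" &
                   !(lv$metabolite %in% c("M001", "M002"))]
  expect_gt(mean(null_q > 0.2, na.rm = TRUE), 0.8)

  sl <- trajectory_slopes(mat)
  expect_equal(nrow(sl), 12 * p)
  tj <- trajectory_demography_assoc(sl, demog)
  hit2 <- tj[tj$metabolite == "M002" & tj$parameter == "mean_lifespan", ]
  expect_lt(hit2$q, 0.2)
  expect_error(level_demography_assoc(mat, demog, age = 99), "no samples")
})

test_that("trajectory slopes are exact on deterministic trends", {
  genos <- rep(c("A", "B"), each = 4)
  ages <- rep(c(4, 10, 24, 45), 2)
  v <- cbind(m1 = 0.01 * ages, m2 = rep(1, 8))
  mat <- tiny_matrix(v, genotype = genos, age_day = ages)
  sl <- trajectory_slopes(mat)
  expect_equal(sl$slope[sl$metabolite == "m1"], rep(0.01, 2),
               tolerance = 1e-12)
  expect_equal(sl$slope[sl$metabolite == "m2"], rep(0, 2), tolerance = 1e-12)
  # a genotype with too few ages is skipped
  mat2 <- tiny_matrix(rbind(v, v[1:2, ]),
                      genotype = c(genos, "C", "C"),
                      age_day = c(ages, 4, 10))
  expect_warning(sl2 <- trajectory_slopes(mat2), "fewer|< 3")
  expect_false("C" %in% sl2$genotype)
})
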