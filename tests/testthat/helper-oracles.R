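# Independent oracle implementations used to verify package results.
# These deliberately share no code with the package internals.

# Proximal-gradient (ISTA) solver for the elastic-net objective
#   (1/2N)||y - b0 - Xb||^2 + l2*((1-l1)||b||^2/2 + l1*||b||_1)
prox_grad_enet <- function(X, y, l1, l2, iters = 200000) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  lip <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                   only.values = TRUE)$values) + l2 * (1 - l1)
  b <- numeric(ncol(X))
  thr <- l2 * l1 / lip
  for (k in seq_len(iters)) {
    g <- drop(crossprod(Xc, Xc %*% b - yc)) / n + l2 * (1 - l1) * b
    b <- b - g / lip
    b <- sign(b) * pmax(abs(b) - thr, 0)
  }
  list(intercept = ybar - sum(xbar * b), beta = b)
}

# Brute-force Benjamini-Hochberg step-up definition:
#   q_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# k-sample log-rank statistic from first principles: at each distinct
# event time, observed vs hypergeometric-expected deaths per group, with
# the full covariance matrix of the (k-1)-vector of O-E sums.
logrank_oracle <- function(time, status, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  times <- sort(unique(time[status == 1]))
  oe <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(status == 1 & time == t)
    ng <- tapply(at_risk, group, sum)
    ng[is.na(ng)] <- 0
    dg <- tapply(status == 1 & time == t, group, sum)
    dg[is.na(dg)] <- 0
    e <- d * ng / n
    oe <- oe + (dg - e)[seq_len(k - 1)]
    if (n > 1) {
      for (a in seq_len(k - 1)) for (b in seq_len(k - 1)) {
        V[a, b] <- V[a, b] +
          d * (n - d) / (n - 1) *
          (ng[a] * ((a == b) * n - ng[b]) / n^2)
      }
    }
  }
  drop(t(oe) %*% solve(V, oe))
}

# Kaplan-Meier restricted mean by explicit step-function enumeration.
km_area_oracle <- function(time, status, tau) {
  ord <- order(time)
  time <- time[ord]
  status <- status[ord]
  times <- sort(unique(time[status == 1]))
  s <- 1
  surv <- numeric(0)
  for (t in times) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_at_risk)
    surv <- c(surv, s)
  }
  grid <- c(0, times[times <= tau], tau)
  sv <- c(1, surv[times <= tau], NA)
  sum(diff(grid) * sv[-length(sv)])
}

# Average-rank Spearman rho from the definition.
spearman_oracle_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small balanced fixtures --------------------------------------------

# A death table written out by hand: counts per (vial, interval).
toy_death_table <- function(genotype = "T", vial = "V1",
                            starts = c(10, 14, 18), ends = c(12, 16, 20),
                            n_dead = c(2, 2, 1), n_censored = NULL) {
  out <- data.frame(genotype = genotype, vial = vial,
                    interval_start = starts, interval_end = ends,
                    n_dead = n_dead, stringsAsFactors = FALSE)
  if (!is.null(n_censored)) out$n_censored <- n_censored
  class(out) <- c("death_table", "data.frame")
  out
}

# Small metabolite matrix with explicit values for model oracles.
tiny_matrix <- function(values, genotype, age_day, normalized = TRUE) {
  n <- nrow(values)
  metabolite_matrix(values,
                    data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                               genotype = genotype, age_day = age_day,
                               replicate = 1L, block = 1L, batch = "B1",
                               stringsAsFactors = FALSE),
                    normalized = normalized)
}
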