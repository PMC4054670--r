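# The Dirichlet-multinomial (DM) model of between-subject community
# variation. A habitat's samples x_i (read counts over K taxa, totals N_i)
# are modelled as multinomial draws around subject-level latent
# compositions that scatter about a mean taxon-frequency vector pi with
# overdispersion theta in [0, 1): theta = 0 collapses to the multinomial
# (every subject shares pi), larger theta means larger between-subject
# variation. Equivalently, the DM concentration vector is
#   a_j = pi_j * (1 - theta) / theta,  A = sum(a) = (1 - theta) / theta,
# so theta = 1 / (1 + A).

#' Bundle DM parameters
#'
#' @param pi probability vector over K taxa (sums to 1, entries >= 0).
#' @param theta overdispersion in [0, 1).
#' @return a `dm_params` list with elements `pi`, `theta`, `K`.
#' @export
dm_params <- function(pi, theta) {
  if (abs(sum(pi) - 1) > 1e-9) .fail("pi must sum to 1 (got %.12f)", sum(pi))
  if (any(pi < 0)) .fail("pi entries must be >= 0")
  if (theta < 0 || theta >= 1) .fail("theta must lie in [0, 1)")
  structure(list(pi = pi, theta = theta, K = length(pi)), class = "dm_params")
}

#' Dirichlet-multinomial log probability mass
#'
#' Log of the DM pmf
#' \deqn{P(X = x) = \frac{N!}{x_1! \cdots x_K!}
#'   \frac{\prod_j \prod_{r=1}^{x_j} [\pi_j(1-\theta) + (r-1)\theta]}
#'        {\prod_{r=1}^{N} [(1-\theta) + (r-1)\theta]}}
#' computed stably through log-gamma identities. At `theta = 0` it equals
#' the multinomial log-pmf exactly (empty products are 1); a taxon with
#' `pi_j = 0` but `x_j > 0` has probability zero and the function returns
#' `-Inf` rather than raising.
#'
#' @param x non-negative integer count vector.
#' @param pi probability vector, same length as `x`.
#' @param theta overdispersion in [0, 1).
#' @return the log probability (possibly `-Inf`).
#' @export
dm_log_pmf <- function(x, pi, theta) {
  if (theta < 0 || theta >= 1) .fail("theta must lie in [0, 1)")
  stopifnot(length(x) == length(pi))
  x <- as.numeric(x)
  n <- sum(x)
  if (any(x > 0 & pi == 0)) return(-Inf)
  coef <- lgamma(n + 1) - sum(lgamma(x + 1))
  if (theta == 0)
    return(coef + sum(x[x > 0] * log(pi[x > 0])))
  a <- pi * (1 - theta) / theta
  A <- (1 - theta) / theta
  pos <- x > 0 # a_j = 0 with x_j = 0 contributes an empty product
  coef + sum(lgamma(a[pos] + x[pos]) - lgamma(a[pos])) -
    (lgamma(A + n) - lgamma(A))
}

# Sum of dm_log_pmf over the rows of a count matrix, parameterised by the
# concentration vector a (all entries > 0). Multinomial coefficients are
# included so the value is comparable with the theta = 0 likelihood.
dm_loglik_conc <- function(m, a) {
  A <- sum(a)
  n <- rowSums(m)
  coef <- sum(lgamma(n + 1)) - sum(lgamma(m + 1))
  coef + sum(lgamma(sweep(m, 2, a, "+")) - rep(lgamma(a), each = nrow(m))) -
    sum(lgamma(A + n) - lgamma(A))
}

# Log-likelihood at (pi, theta) for a count matrix, handling theta == 0 and
# zero pi entries by the dm_log_pmf conventions.
dm_loglik <- function(m, pi, theta) {
  sum(apply(m, 1, dm_log_pmf, pi = pi, theta = theta))
}

#' Method-of-moments fit of the DM model
#'
#' `pi` is estimated by read-pooled proportions (weighting subjects by
#' depth). `theta` solves the pooled second-moment condition implied by
#' \eqn{Var(x_{ij}/N_i) = \pi_j(1-\pi_j)[1 + (N_i - 1)\theta]/N_i},
#' pooling across taxa by summing numerators and denominators (robust when
#' many taxa are rare). A negative raw estimate (underdispersed data) is
#' clamped to 0 with a warning.
#'
#' @param table a [taxon_table()] with at least 2 samples.
#' @return a `dm_fit` list: `params` ([dm_params()]), `log_likelihood`,
#'   `theta_se` (`NA`; see [fit_mle()] for bootstrap SEs), `method`,
#'   `n_subjects`.
#' @export
fit_moments <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  m <- unclass_tt(table)
  if (nrow(m) < 2) .fail("need >= 2 samples to estimate variation")
  nt <- rowSums(m)
  if (any(nt < 1)) .fail("every sample needs >= 1 read")
  pi_hat <- colSums(m) / sum(nt)
  p <- sweep(m, 1, nt, "/")
  dev2 <- sweep(p, 2, pi_hat, "-")^2          # (p_ij - pi_j)^2
  v <- pi_hat * (1 - pi_hat)                  # per-taxon variance scale
  s_inv <- sum(1 / nt)                        # sum_i 1/N_i
  s_frac <- sum((nt - 1) / nt)                # sum_i (N_i - 1)/N_i
  num <- sum(colSums(dev2)) - sum(v) * s_inv
  den <- sum(v) * s_frac
  theta_hat <- if (den > 0) num / den else 0
  if (theta_hat < 0) {
    warning("moment estimate of theta is negative (underdispersed data); clamped to 0")
    theta_hat <- 0
  }
  theta_hat <- min(theta_hat, 1 - 1e-8)
  params <- dm_params(pi_hat, theta_hat)
  structure(list(params = params,
                 log_likelihood = dm_loglik(m, pi_hat, theta_hat),
                 theta_se = NA_real_, method = "moments",
                 n_subjects = nrow(m)),
            class = "dm_fit")
}

# Core MLE on a count matrix whose columns all have positive totals.
# Optimises log a (unconstrained) by BFGS with the analytic gradient
#   dL/da_j = sum_i [digamma(a_j + x_ij) - digamma(a_j)
#                    - digamma(A + N_i) + digamma(A)].
fit_mle_matrix <- function(m, init_pi, init_theta, maxit = 500) {
  nt <- rowSums(m)
  init_theta <- min(max(init_theta, 1e-4), 0.99)
  init_pi <- pmax(init_pi, 1e-8); init_pi <- init_pi / sum(init_pi)
  negll <- function(v) -dm_loglik_conc(m, exp(v))
  grad <- function(v) {
    a <- exp(v); A <- sum(a)
    g <- colSums(digamma(sweep(m, 2, a, "+"))) - nrow(m) * digamma(a) -
      sum(digamma(A + nt) - digamma(A))
    -g * a
  }
  # box the log-concentrations: beyond exp(16) the lgamma differences lose
  # precision to cancellation (theta is then < 1e-7, i.e. multinomial to
  # working precision), and below exp(-25) a taxon is numerically absent
  v0 <- pmin(pmax(log(init_pi * (1 - init_theta) / init_theta), -24), 15)
  opt <- stats::optim(v0, negll, grad, method = "L-BFGS-B",
                      lower = -25, upper = 16,
                      control = list(maxit = maxit, factr = 10))
  a <- exp(opt$par); A <- sum(a)
  list(pi = a / A, theta = 1 / (1 + A), log_likelihood = -opt$value,
       convergence = opt$convergence)
}

#' Maximum-likelihood fit of the DM model
#'
#' Maximises the DM log-likelihood over the simplex x [0, 1) in the
#' unconstrained log-concentration parameterisation, initialised from
#' [fit_moments()] unless `init` is given. Taxa absent from every sample
#' are dropped before fitting (their `pi` entries are reported as 0); a
#' degenerate simplex over padded zeros would otherwise break the
#' optimiser. If the optimum lies on the `theta = 0` boundary the
#' moments/multinomial fit can dominate the interior iterate; the better of
#' the two is returned, so the MLE log-likelihood never falls below the
#' moments fit. `theta_se` is a nonparametric bootstrap over subjects.
#'
#' @param table a [taxon_table()] with at least 2 samples.
#' @param init optional [dm_params()] initial value.
#' @param n_boot bootstrap replicates for `theta_se` (0 skips; default 0,
#'   use [theta_bootstrap()] or `n_boot = 200` for the reported SEs).
#' @param seed seed for the bootstrap resampling.
#' @return a `dm_fit` list as in [fit_moments()], `method = "mle"`.
#' @export
fit_mle <- function(table, init = NULL, n_boot = 0, seed = 1) {
  stopifnot(inherits(table, "taxon_table"))
  m <- unclass_tt(table)
  if (nrow(m) < 2) .fail("need >= 2 samples to estimate variation")
  observed <- colSums(m) > 0
  mm <- m[, observed, drop = FALSE]
  mom <- fit_moments(table)
  if (is.null(init)) {
    init_pi <- mom$params$pi[observed]
    init_theta <- mom$params$theta
  } else {
    init_pi <- init$pi[observed]
    init_theta <- init$theta
  }
  fit <- fit_mle_matrix(mm, init_pi / sum(init_pi), init_theta)
  mom_ll <- mom$log_likelihood
  if (fit$log_likelihood < mom_ll) {
    # optimum is at/near the theta = 0 boundary; report the dominating fit
    pi_full <- mom$params$pi
    theta <- mom$params$theta
    ll <- mom_ll
  } else {
    pi_full <- numeric(ncol(m)); names(pi_full) <- colnames(m)
    pi_full[observed] <- fit$pi
    theta <- fit$theta
    ll <- fit$log_likelihood
  }
  se <- NA_real_
  if (n_boot > 0)
    se <- stats::sd(theta_bootstrap(table, n_boot = n_boot, seed = seed))
  structure(list(params = dm_params(unname(pi_full), theta),
                 log_likelihood = ll, theta_se = se, method = "mle",
                 n_subjects = nrow(m)),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("DM fit (%s): K = %d taxa, n = %d subjects\n",
              x$method, x$params$K, x$n_subjects))
  cat(sprintf("  theta = %.4f%s   logLik = %.2f\n", x$params$theta,
              if (is.na(x$theta_se)) "" else sprintf(" (SE %.4f)", x$theta_se),
              x$log_likelihood))
  invisible(x)
}

#' Bootstrap replicates of the theta estimate
#'
#' Resamples subjects (rows) with replacement and refits by maximum
#' likelihood; the SD of the replicates is the reported uncertainty of
#' theta and their percentiles give interval estimates.
#'
#' @param table a [taxon_table()].
#' @param n_boot number of replicates, default 200.
#' @param seed integer seed.
#' @return numeric vector of `n_boot` theta estimates.
#' @export
theta_bootstrap <- function(table, n_boot = 200, seed = 1) {
  m <- unclass_tt(table)
  mom <- fit_moments(table)
  vapply(seq_len(n_boot), function(b) {
    idx <- with_seed(derive_seed(seed, "boot", b),
                     sample.int(nrow(m), nrow(m), replace = TRUE))
    mb <- m[idx, , drop = FALSE]
    obs <- colSums(mb) > 0
    mb <- mb[, obs, drop = FALSE]
    pi0 <- pmax(colSums(mb) / sum(mb), 1e-8); pi0 <- pi0 / sum(pi0)
    fit_mle_matrix(mb, pi0, mom$params$theta)$theta
  }, numeric(1))
}

#' Overdispersion across rarefaction depths
#'
#' Rarefies the table to each requested depth, fits theta by maximum
#' likelihood at each, and assesses equality across depths by overlap of
#' the per-depth 95% bootstrap percentile intervals: theta is a population
#' parameter of the community, not of the sequencing depth, so on
#' DM-distributed data the per-depth estimates should agree.
#'
#' @param table a [taxon_table()]; every sample needs `>= max(depths)` reads.
#' @param depths read depths, default `c(1000, 3000, 6000, 9000)`.
#' @param seed integer seed (rarefaction and bootstrap).
#' @param n_boot bootstrap replicates per depth, default 200.
#' @return list: `fits` (data.frame of depth, theta, se, ci_lo, ci_hi,
#'   log_likelihood), `consistent` (logical: all interval pairs overlap).
#' @export
theta_across_depths <- function(table, depths = c(1000, 3000, 6000, 9000),
                                seed = 1, n_boot = 200) {
  nt <- read_totals(table)
  if (any(nt < max(depths)))
    .fail("samples below max depth %d: %s", max(depths),
          paste(rownames(table)[nt < max(depths)], collapse = ", "))
  rows <- lapply(depths, function(d) {
    rt <- rarefy_table(table, depth = d, seed = derive_seed(seed, "depth", d))
    fit <- fit_mle(rt)
    boots <- theta_bootstrap(rt, n_boot = n_boot,
                             seed = derive_seed(seed, "boot-depth", d))
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    data.frame(depth = d, theta = fit$params$theta, se = stats::sd(boots),
               ci_lo = ci[1], ci_hi = ci[2],
               log_likelihood = fit$log_likelihood)
  })
  fits <- do.call(rbind, rows)
  if (nrow(fits) < 2) return(list(fits = fits, consistent = TRUE))
  pairs <- utils::combn(nrow(fits), 2)
  overlap <- apply(pairs, 2, function(ij) {
    fits$ci_lo[ij[1]] <= fits$ci_hi[ij[2]] && fits$ci_lo[ij[2]] <= fits$ci_hi[ij[1]]
  })
  list(fits = fits, consistent = all(overlap))
}
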