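# Bayesian age-period-cohort model for DALY (or incidence/mortality) rate
# grids: Poisson likelihood, log-linear predictor mu + alpha_i + beta_j +
# gamma_k with cohort index k = (n_age - i) + j, second-order random-walk
# (RW2) smoothing priors on the three effect vectors and inverse-gamma
# hyperpriors on their variances.
#
# Inference is Metropolis-within-Gibbs: the latent effects are updated
# jointly with a Gaussian proposal taken from a one-step penalized-IRLS
# (Laplace) approximation at the current state, Metropolis-corrected; the
# RW2 variances have conjugate inverse-gamma full conditionals. The APC
# identifiability ambiguity (a shared linear trend that can shuttle between
# age, period and cohort) is resolved by sum-to-zero constraints on all
# three effects plus one zero-linear-trend constraint, placed on the cohort
# effect by default so the drift is carried by the period effect.

# RW2 structure matrix K = t(D2) %*% D2 (rank n - 2).
rw2_structure <- function(n) {
  if (n < 3) return(diag(0, n))
  D <- diff(diag(n), differences = 2)
  crossprod(D)
}

# Orthonormal basis of the subspace orthogonal to the columns of A.
null_basis <- function(n, A) {
  if (is.null(A)) return(diag(n))
  q <- qr(cbind(A))
  qr.Q(q, complete = TRUE)[, (q$rank + 1):n, drop = FALSE]
}

#' Fit a Bayesian age-period-cohort model to a count grid
#'
#' Fits the log-linear Poisson rate model
#' \deqn{\log \lambda_{ij} = \mu + \alpha_i + \beta_j + \gamma_k, \quad
#'   k = (n_{age} - i) + j,}
#' with RW2 smoothing priors on the age (\eqn{\alpha}), period (\eqn{\beta})
#' and cohort (\eqn{\gamma}) effects, inverse-gamma hyperpriors on the RW2
#' variances, and a vague normal prior on \eqn{\mu}. Counts in cell (i, j)
#' are Poisson with mean \code{exposure[i,j] * lambda[i,j]}.
#'
#' @param counts Non-negative integer matrix, ages in rows, periods in
#'   columns; at least 5 ages and 8 periods.
#' @param exposure Strictly positive matrix of person-years, same shape.
#' @param prior Hyperprior settings: list with \code{a}, \code{b}
#'   (inverse-gamma shape and rate for the three RW2 variances) and
#'   \code{mu_prec} (precision of the \eqn{\mu} prior).
#' @param drift_in Where the shared linear trend is carried:
#'   \code{"period"} (default; cohort effect is detrended) or
#'   \code{"cohort"} (period effect is detrended).
#' @param n_iter,burn Total MCMC iterations and burn-in discarded.
#' @param seed Integer seed for the sampler.
#' @return An object of class \code{"bapc"} with posterior draws, posterior
#'   summaries (\code{$effects}: mean, sd, 2.5/97.5 percentiles of mu,
#'   alpha, beta, gamma), \code{$variances}, fitted rate grid
#'   (\code{$fitted_rates}, posterior means), and sampler diagnostics
#'   (\code{$diagnostics}: acceptance rate, effective sample size of mu).
#' @seealso \code{\link{predict.bapc}} for forecasting,
#'   \code{\link{gen_apc_counts}} for simulating grids with known truth.
#' @export
bapc <- function(counts, exposure,
                 prior = list(a = 1, b = 5e-5, mu_prec = 1e-6),
                 drift_in = c("period", "cohort"),
                 n_iter = 3000, burn = 1000, seed = 1L) {
  drift_in <- match.arg(drift_in)
  counts <- as.matrix(counts); exposure <- as.matrix(exposure)
  if (!all(dim(counts) == dim(exposure)))
    stop("counts and exposure must have identical dimensions")
  if (nrow(counts) < 5 || ncol(counts) < 8)
    stop("grid must be at least 5 ages x 8 periods")
  if (any(exposure <= 0)) stop("exposure must be strictly positive")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (burn >= n_iter) stop("burn must be smaller than n_iter")

  A <- nrow(counts); P <- ncol(counts); K <- A + P - 1
  y <- as.vector(counts); E <- as.vector(exposure)
  i_idx <- rep(seq_len(A), P)
  j_idx <- rep(seq_len(P), each = A)
  k_idx <- (A - i_idx) + j_idx

  # constrained bases: sum-to-zero everywhere, detrend one effect
  ones <- function(n) matrix(1, n, 1)
  lin <- function(n) cbind(1, seq_len(n) - (n + 1) / 2)
  Za <- null_basis(A, ones(A))
  Zb <- if (drift_in == "cohort") null_basis(P, lin(P)) else
    null_basis(P, ones(P))
  Zg <- if (drift_in == "period") null_basis(K, lin(K)) else
    null_basis(K, ones(K))
  qa <- ncol(Za); qb <- ncol(Zb); qg <- ncol(Zg)
  q <- 1L + qa + qb + qg
  iz_mu <- 1L
  iz_a <- 1L + seq_len(qa)
  iz_b <- 1L + qa + seq_len(qb)
  iz_g <- 1L + qa + qb + seq_len(qg)

  # cell-level design in the constrained parameterisation
  B <- matrix(0, A * P, q)
  B[, iz_mu] <- 1
  B[, iz_a] <- Za[i_idx, , drop = FALSE]
  B[, iz_b] <- Zb[j_idx, , drop = FALSE]
  B[, iz_g] <- Zg[k_idx, , drop = FALSE]

  Ka <- rw2_structure(A); Kp <- rw2_structure(P); Kg <- rw2_structure(K)
  KaZ <- crossprod(Za, Ka %*% Za)
  KpZ <- crossprod(Zb, Kp %*% Zb)
  KgZ <- crossprod(Zg, Kg %*% Zg)
  rank_a <- A - 2; rank_p <- P - 2; rank_g <- K - 2

  prec_z <- function(s2) {
    Q <- matrix(0, q, q)
    Q[iz_mu, iz_mu] <- prior$mu_prec
    Q[iz_a, iz_a] <- KaZ / s2[1]
    Q[iz_b, iz_b] <- KpZ / s2[2]
    Q[iz_g, iz_g] <- KgZ / s2[3]
    Q
  }
  log_post <- function(z, Q) {
    eta <- pmin(as.vector(B %*% z), 40)
    sum(y * eta - E * exp(eta)) - 0.5 * sum(z * (Q %*% z))
  }
  # Gaussian (Laplace) approximation at z: one Newton step
  gauss_approx <- function(z, Q) {
    eta <- pmin(as.vector(B %*% z), 40)
    m <- E * exp(eta)
    g <- crossprod(B, y - m) - Q %*% z
    H <- crossprod(B * sqrt(m)) + Q
    R <- chol(H)
    mean_ <- z + backsolve(R, backsolve(R, g, transpose = TRUE))
    list(mean = as.vector(mean_), R = R,
         half_logdet = sum(log(diag(R))))
  }
  prop_logdens <- function(ga, z) {
    d <- ga$R %*% (z - ga$mean)
    ga$half_logdet - 0.5 * sum(d^2)
  }

  with_seed(seed, {
    s2 <- c(0.1, 0.1, 0.1)
    Q <- prec_z(s2)
    # start at the penalized-likelihood mode
    z <- rep(0, q)
    for (it in 1:50) {
      ga <- gauss_approx(z, Q)
      if (max(abs(ga$mean - z)) < 1e-8) { z <- ga$mean; break }
      z <- ga$mean
    }
    keep <- n_iter - burn
    draws_z <- matrix(0, keep, q)
    draws_s2 <- matrix(0, keep, 3,
                       dimnames = list(NULL, c("age", "period", "cohort")))
    acc <- 0L
    lp <- log_post(z, Q)
    ga <- gauss_approx(z, Q)
    for (it in seq_len(n_iter)) {
      # latent-effects update: MH with Laplace proposal
      zs <- ga$mean + backsolve(ga$R, stats::rnorm(q))
      lps <- log_post(zs, Q)
      gas <- gauss_approx(zs, Q)
      lr <- (lps - lp) + (prop_logdens(gas, z) - prop_logdens(ga, zs))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        z <- zs; lp <- lps; ga <- gas; acc <- acc + 1L
      }
      # conjugate inverse-gamma variance updates
      a_ <- Za %*% z[iz_a]; b_ <- Zb %*% z[iz_b]; g_ <- Zg %*% z[iz_g]
      s2[1] <- 1 / stats::rgamma(1, prior$a + rank_a / 2,
                                 prior$b + 0.5 * crossprod(a_, Ka %*% a_))
      s2[2] <- 1 / stats::rgamma(1, prior$a + rank_p / 2,
                                 prior$b + 0.5 * crossprod(b_, Kp %*% b_))
      s2[3] <- 1 / stats::rgamma(1, prior$a + rank_g / 2,
                                 prior$b + 0.5 * crossprod(g_, Kg %*% g_))
      Q <- prec_z(s2)
      lp <- log_post(z, Q)
      ga <- gauss_approx(z, Q)
      if (it > burn) {
        draws_z[it - burn, ] <- z
        draws_s2[it - burn, ] <- s2
      }
    }

    # map draws back to the natural parameterisation
    mu_d <- draws_z[, iz_mu]
    alpha_d <- draws_z[, iz_a, drop = FALSE] %*% t(Za)
    beta_d <- draws_z[, iz_b, drop = FALSE] %*% t(Zb)
    gamma_d <- draws_z[, iz_g, drop = FALSE] %*% t(Zg)
    summ <- function(d) {
      d <- as.matrix(d)
      data.frame(mean = colMeans(d), sd = apply(d, 2, stats::sd),
                 q025 = apply(d, 2, stats::quantile, 0.025),
                 q975 = apply(d, 2, stats::quantile, 0.975))
    }
    eta_mean <- colMeans(exp(pmin(draws_z %*% t(B), 40)))
    fitted_rates <- matrix(eta_mean, A, P, dimnames = dimnames(counts))
    ac <- stats::acf(mu_d, plot = FALSE, lag.max = 50)$acf[-1]
    pos <- which(ac < 0.05)[1]
    ess_mu <- length(mu_d) /
      (1 + 2 * sum(ac[seq_len(if (is.na(pos)) 50 else pos)]))
    structure(list(
      effects = list(mu = summ(mu_d), alpha = summ(alpha_d),
                     beta = summ(beta_d), gamma = summ(gamma_d)),
      variances = summ(draws_s2),
      fitted_rates = fitted_rates,
      draws = list(mu = mu_d, alpha = alpha_d, beta = beta_d,
                   gamma = gamma_d, s2 = draws_s2),
      diagnostics = list(acceptance_rate = acc / n_iter, ess_mu = ess_mu),
      data = list(counts = counts, exposure = exposure),
      meta = list(n_age = A, n_period = P, drift_in = drift_in,
                  prior = prior, n_iter = n_iter, burn = burn, seed = seed,
                  engine = "mwg-laplace-mcmc")),
      class = "bapc")
  })
}

#' @export
print.bapc <- function(x, ...) {
  cat(sprintf("Bayesian APC fit: %d ages x %d periods (%s)\n",
              x$meta$n_age, x$meta$n_period, x$meta$engine))
  cat(sprintf("  mu: %.3f (95%% CrI %.3f to %.3f)\n",
              x$effects$mu$mean, x$effects$mu$q025, x$effects$mu$q975))
  cat(sprintf("  RW2 sd (posterior means): age %.4f, period %.4f, cohort %.4f\n",
              sqrt(mean(x$draws$s2[, 1])), sqrt(mean(x$draws$s2[, 2])),
              sqrt(mean(x$draws$s2[, 3]))))
  cat(sprintf("  MH acceptance %.2f, ESS(mu) %.0f\n",
              x$diagnostics$acceptance_rate, x$diagnostics$ess_mu))
  invisible(x)
}

#' @export
summary.bapc <- function(object, ...) {
  structure(list(effects = object$effects, variances = object$variances,
                 diagnostics = object$diagnostics, meta = object$meta),
            class = "summary.bapc")
}

#' @export
print.summary.bapc <- function(x, ...) {
  cat("Posterior effect summaries (mean, sd, 95% CrI)\n")
  for (nm in c("mu", "alpha", "beta", "gamma")) {
    cat(nm, ":\n", sep = "")
    print(round(x$effects[[nm]], 4))
  }
  cat("RW2 variance summaries:\n"); print(signif(x$variances, 4))
  cat(sprintf("Acceptance %.2f, ESS(mu) %.0f\n",
              x$diagnostics$acceptance_rate, x$diagnostics$ess_mu))
  invisible(x)
}

#' @export
coef.bapc <- function(object, ...) {
  list(mu = object$effects$mu$mean,
       alpha = object$effects$alpha$mean,
       beta = object$effects$beta$mean,
       gamma = object$effects$gamma$mean)
}

#' @export
fitted.bapc <- function(object, ...) object$fitted_rates

#' Forecast rates from a Bayesian APC fit
#'
#' Extrapolates the period effect (and the cohort effects entering future
#' cells) under the RW2 predictive distribution, per posterior draw, and
#' summarises the resulting rate grid for the next \code{horizon} periods.
#' Credible intervals widen with horizon as the random-walk predictive
#' variance accumulates.
#'
#' @param object A \code{\link{bapc}} fit.
#' @param horizon Number of future periods (>= 1).
#' @param n_sim Forecast path simulations per posterior draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List with \code{median}, \code{mean}, \code{lower}, \code{upper}
#'   (age x horizon matrices of rates, 95\% credible bounds) and
#'   \code{horizon}.
#' @export
predict.bapc <- function(object, horizon = 1, n_sim = 2, seed = 1L, ...) {
  if (horizon < 1) stop("horizon must be >= 1")
  A <- object$meta$n_age; P <- object$meta$n_period
  K <- A + P - 1
  max_k <- A - 1 + P + horizon   # deepest future cohort needed
  d <- object$draws
  n_draw <- length(d$mu)
  with_seed(seed, {
    n_tot <- n_draw * n_sim
    out <- array(NA_real_, c(n_tot, A, horizon))
    row <- 0L
    for (s in seq_len(n_sim)) {
      for (dr in seq_len(n_draw)) {
        row <- row + 1L
        sp <- sqrt(d$s2[dr, 2]); sg <- sqrt(d$s2[dr, 3])
        beta <- d$beta[dr, ]; gamma <- d$gamma[dr, ]
        for (h in seq_len(horizon)) {
          nb <- length(beta)
          beta <- c(beta, 2 * beta[nb] - beta[nb - 1] +
                      stats::rnorm(1, 0, sp))
        }
        while (length(gamma) < max_k) {
          ng <- length(gamma)
          gamma <- c(gamma, 2 * gamma[ng] - gamma[ng - 1] +
                       stats::rnorm(1, 0, sg))
        }
        for (h in seq_len(horizon)) {
          j <- P + h
          k <- (A - seq_len(A)) + j
          out[row, , h] <- exp(pmin(d$mu[dr] + d$alpha[dr, ] +
                                      beta[P + h] + gamma[k], 40))
        }
      }
    }
    qfun <- function(p) apply(out, c(2, 3), stats::quantile, p)
    list(median = qfun(0.5), mean = apply(out, c(2, 3), mean),
         lower = qfun(0.025), upper = qfun(0.975), horizon = horizon)
  })
}

#' @export
plot.bapc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- list(alpha = "Age effect", beta = "Period effect",
                 gamma = "Cohort effect")
  for (nm in names(panels)) {
    e <- x$effects[[nm]]
    idx <- seq_len(nrow(e))
    graphics::plot(idx, e$mean, type = "l", xlab = "index",
                   ylab = "effect (log-rate)", main = panels[[nm]], ...)
    graphics::lines(idx, e$q025, lty = 2)
    graphics::lines(idx, e$q975, lty = 2)
  }
  invisible(x)
}
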