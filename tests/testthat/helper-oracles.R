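# Independent oracle implementations used to cross-check the package.
# These are deliberate straight-line transcriptions of the model equations
# and brute-force numerical routines, sharing no code with the package
# internals.

# ---- trial-by-trial replay of the hybrid learner ------------------------

# par: list(alpha, lam, eta, eta_cf, beta, pi, rho, omega named by cell)
# d: behavior-table data frame with a `cell` column of cell names
oracle_replay <- function(par, d, known = FALSE) {
  Q1 <- matrix(4.5, 2, 2)
  Q2 <- c(4.5, 4.5)
  Tr <- matrix(0.5, 2, 2) # P(planet 1 | state, action)
  if (known) {
    d1 <- c(d$map1[1], d$map2[1])
    for (s in 1:2) {
      Tr[s, 1] <- as.numeric(d1[s] == 1)
      Tr[s, 2] <- as.numeric(d1[s] == 2)
    }
  }
  prev_state <- NA
  prev_action <- NA
  prev_key <- NA
  ll <- 0
  p_chosen <- rep(NA_real_, nrow(d))
  for (t in seq_len(nrow(d))) {
    if (d$missing_stage1[t] == 1) {
      prev_state <- NA; prev_action <- NA; prev_key <- NA
      next
    }
    s <- d$s1[t]; a <- d$a1[t]; k <- d$key1[t]; pl <- d$s2[t]
    w <- par$omega[[d$cell[t]]]
    val <- numeric(2)
    for (aa in 1:2) {
      qmb <- Tr[s, aa] * Q2[1] + (1 - Tr[s, aa]) * Q2[2]
      q <- (1 - w) * Q1[s, aa] + w * qmb
      rep_i <- isTRUE(prev_state == s && prev_action == aa)
      key_aa <- if ((k == 1) == (aa == a)) 1 else 2
      resp_i <- isTRUE(key_aa == prev_key)
      val[aa] <- par$beta * (q + par$pi * rep_i + par$rho * resp_i)
    }
    p <- exp(val - max(val))
    p <- p / sum(p)
    ll <- ll + log(p[a])
    p_chosen[t] <- p[a]
    # eligibility traces reset at trial start; stage-1 backup with r = 0
    e1 <- matrix(0, 2, 2); e2 <- c(0, 0)
    e1[s, a] <- 1
    delta <- 0 + Q2[pl] - Q1[s, a]
    Q1 <- Q1 + par$alpha * e1 * delta
    Q2 <- Q2 + par$alpha * e2 * delta
    e1 <- e1 * par$lam; e2 <- e2 * par$lam
    if (!known) {
      eta <- if (d$transition_condition[t] == "stable") 1 else par$eta
      eta_cf <- if (d$transition_condition[t] == "stable") 1 else par$eta_cf
      if (pl == 1) {
        Tr[s, a] <- Tr[s, a] + eta * (1 - Tr[s, a])
      } else {
        Tr[s, a] <- Tr[s, a] * (1 - eta)
      }
      ao <- 3 - a
      if (pl == 2) {
        # counterfactual action must lead to planet 1
        Tr[s, ao] <- Tr[s, ao] + eta_cf * (1 - Tr[s, ao])
      } else {
        Tr[s, ao] <- Tr[s, ao] * (1 - eta_cf)
      }
    }
    if (d$missing_stage2[t] == 0) {
      e2[pl] <- 1
      delta2 <- d$reward[t] + 0 - Q2[pl]
      Q1 <- Q1 + par$alpha * e1 * delta2
      Q2 <- Q2 + par$alpha * e2 * delta2
    }
    prev_state <- s; prev_action <- a; prev_key <- k
  }
  list(loglik = ll, Q1 = Q1, Q2 = Q2, Tr = Tr, p_chosen = p_chosen)
}

params_as_list <- function(p) {
  list(alpha = p$alpha, lam = p$lam, eta = p$eta, eta_cf = p$eta_cf,
       beta = p$beta, pi = p$pi, rho = p$rho, omega = p$omega)
}

behavior_with_cells <- function(b) {
  d <- as.data.frame(b)
  d$cell <- condition_cells(b, attr(b, "layout"))
  d
}

# ---- stretched-beta correlation Bayes factor by brute-force quadrature ---

# 2F1(1/2, 1/2; c; x) through its Euler integral with the substitution
# t = u^2 (removing the endpoint singularity), evaluated by fixed
# Gauss-Legendre quadrature; vectorized over x.
oracle_hyp2f1_half <- function(c_par, x, nodes = 160L) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  u <- gl$x; wq <- gl$w
  base <- (1 - u^2)^(c_par - 1.5)
  inner <- vapply(x, function(xx) {
    2 * sum(wq * base / sqrt(1 - xx * u^2))
  }, numeric(1))
  inner * exp(lgamma(c_par) - lgamma(0.5) - lgamma(c_par - 0.5))
}

oracle_bf_corr <- function(r, n, kappa, side = "two_sided",
                           n_grid = 20001L) {
  lims <- switch(side,
    two_sided = c(-1, 1, 1),
    negative = c(-1, 0, 2),
    positive = c(0, 1, 2)
  )
  rho <- seq(lims[1] + 1e-9, lims[2] - 1e-9, length.out = n_grid)
  c_par <- n - 0.5
  f <- oracle_hyp2f1_half(c_par, (1 + rho * r) / 2)
  f0 <- oracle_hyp2f1_half(c_par, 0.5)
  lr <- exp((n - 1) / 2 * log(1 - rho^2) +
              (1.5 - n) * log(1 - rho * r)) * f / f0
  a <- 1 / kappa
  prior <- (1 - rho^2)^(a - 1) / (2^(2 * a - 1) * beta(a, a))
  h <- rho[2] - rho[1]
  integral <- h * (sum(lr * prior) - 0.5 * (lr[1] * prior[1] +
                                              lr[n_grid] * prior[n_grid]))
  lims[3] * integral
}

# ---- JZS paired t-test Bayes factor via the g-mixture integral ----------

oracle_bf_ttest <- function(t, n, rscale) {
  nu <- n - 1
  num <- stats::integrate(function(g) {
    (1 + n * g * rscale^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * rscale^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

# ---- stationary mean of the reflected Gaussian walk ---------------------

# transition kernel discretized on a regular grid; reflection handled by
# folding the normal increment's images back into the interval
oracle_walk_stationary_mean <- function(sd, lower, upper, step = 0.01) {
  x <- seq(lower, upper, by = step)
  m <- length(x)
  span <- upper - lower
  K <- matrix(0, m, m)
  for (k in -3:3) {
    # images y + 2*span*k and (2*lower - y) + 2*span*k
    K <- K + outer(x, x, function(from, to) {
      stats::dnorm(to + 2 * span * k - from, 0, sd)
    })
    K <- K + outer(x, x, function(from, to) {
      stats::dnorm(2 * lower - to + 2 * span * k - from, 0, sd)
    })
  }
  K <- K / rowSums(K)
  v <- rep(1 / m, m)
  for (i in 1:400) v <- as.vector(v %*% K)
  sum(v * x)
}
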