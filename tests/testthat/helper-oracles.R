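# Independent oracles used to verify the ADMM solver and its proximal
# operator. These deliberately avoid the package's own computational path:
# the objective oracle minimises a smoothed objective with stats::optim
# (L-BFGS-B), the prox oracle runs Douglas-Rachford splitting built only on
# an inline single-block soft-threshold, and per-study MLEs come from
# stats::glm.fit.

# random small multi-study instance with a mild planted signal
rand_instance <- function(seed, p = 8, K = 2, n = 40, G = 2) {
  set.seed(seed)
  X <- lapply(seq_len(K), function(k) matrix(rnorm(n * p), n, p))
  beta <- matrix(0, p, K)
  beta[seq_len(min(3, p)), ] <- rnorm(min(3, p) * K, sd = 0.8)
  y <- lapply(seq_len(K), function(k) {
    repeat {
      yk <- rbinom(n, 1, plogis(X[[k]] %*% beta[, k]))
      if (any(yk == 0) && any(yk == 1)) return(yk)
    }
  })
  data <- multistudy_dataset(X, y)
  groups <- group_structure(rep(seq_len(G), each = ceiling(p / G))[seq_len(p)])
  list(data = data, groups = groups)
}

# smoothed-objective value oracle: sqrt(s) terms replaced by
# sqrt(s + mu^2) - mu (error bounded by mu times the summed penalty
# weights), minimised by L-BFGS-B with an analytic gradient
oracle_objective_min <- function(data, groups, cfg, mu = 1e-6) {
  p <- data$p; K <- data$K
  gamma <- cfg$group_weights
  if (is.null(gamma)) gamma <- sqrt(groups$sizes)
  kappa <- cfg$row_weights
  if (is.null(kappa)) kappa <- rep(1, p)
  lam1 <- (1 - cfg$alpha) * cfg$lambda
  lam2 <- cfg$alpha * cfg$lambda
  gidx <- groups$index

  fn <- function(par) {
    B <- matrix(par, p, K)
    nll <- 0
    for (k in seq_len(K)) {
      eta <- data$X[[k]] %*% B[, k]
      nll <- nll + sum(log1p(exp(-abs(eta))) + pmax(eta, 0) -
                         data$y[[k]] * eta)
    }
    rss <- rowSums(B^2)
    gss <- as.numeric(rowsum(rss, gidx))
    nll + lam1 * sum(gamma * (sqrt(gss + mu^2) - mu)) +
      lam2 * sum(kappa * (sqrt(rss + mu^2) - mu))
  }
  gr <- function(par) {
    B <- matrix(par, p, K)
    Gm <- matrix(0, p, K)
    for (k in seq_len(K)) {
      eta <- data$X[[k]] %*% B[, k]
      Gm[, k] <- crossprod(data$X[[k]], plogis(eta) - data$y[[k]])
    }
    rss <- rowSums(B^2)
    gss <- as.numeric(rowsum(rss, gidx))
    grow <- lam2 * kappa / sqrt(rss + mu^2)
    ggrp <- (lam1 * gamma / sqrt(gss + mu^2))[gidx]
    as.numeric(Gm + B * (grow + ggrp))
  }
  opt <- stats::optim(rep(0, p * K), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 5000, factr = 10))
  list(value = opt$value, B = matrix(opt$par, p, K),
       convergence = opt$convergence)
}

# Douglas-Rachford prox oracle for
#   argmin_Z  0.5 * ||V - Z||_F^2
#           + sum_j t_row[j] ||Z_j.||  +  sum_g t_grp[g] ||Z_(pi_g,.)||_F
# split as f(Z) = quadratic + row norms, g(Z) = group norms.
oracle_prox_dr <- function(V, groups, t_row, t_grp, iters = 4000) {
  bst <- function(A, t) {            # single-block soft threshold, inline
    nrm <- sqrt(sum(A^2))
    if (nrm <= t) A * 0 else A * ((nrm - t) / nrm)
  }
  prox_f <- function(W, s = 1) {     # rows: quadratic + row-norm prox
    out <- W
    for (j in seq_len(nrow(W)))
      out[j, ] <- bst((W[j, ] + s * V[j, ]) / (1 + s), s * t_row[j] / (1 + s))
    out
  }
  prox_g <- function(W, s = 1) {
    out <- W
    for (g in seq_along(groups$groups)) {
      set <- groups$groups[[g]]
      out[set, ] <- bst(W[set, , drop = FALSE], s * t_grp[g])
    }
    out
  }
  Y <- V
  for (it in seq_len(iters)) {
    Xp <- prox_f(Y)
    Zp <- prox_g(2 * Xp - Y)
    Y <- Y + Zp - Xp
    if (it %% 50 == 0 && sqrt(sum((Zp - Xp)^2)) < 1e-12) break
  }
  prox_f(Y)
}

# reference per-study logistic MLE
ref_glm_coef <- function(X, y) {
  suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))$coefficients
}

# central finite differences of a scalar function of a matrix
fd_gradient <- function(f, B, h = 1e-5) {
  G <- B * 0
  for (i in seq_along(B)) {
    Bp <- B; Bm <- B
    Bp[i] <- Bp[i] + h
    Bm[i] <- Bm[i] - h
    G[i] <- (f(Bp) - f(Bm)) / (2 * h)
  }
  G
}

# independent confusion-matrix implementation via table()
ref_confusion_metrics <- function(truth, called) {
  tab <- table(factor(truth, c(FALSE, TRUE)), factor(called, c(FALSE, TRUE)))
  tn <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tp <- tab[2, 2]
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  list(tpr = tp / (tp + fn), tnr = tn / (tn + fp),
       mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0)
}
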