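# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense linear algebra for the smoothing spline,
# explicit enumeration for bipartitions, fine-step integration for the
# culture mean model.

# Exact natural cubic smoothing spline minimizing
#   p * sum (y - f(x))^2 + (1 - p) * integral f''^2,
# solved densely in the classic Reinsch form; returns fitted values at the
# knots and the interior second derivatives.
reinsch_smooth <- function(x, y, p) {
  n <- length(x)
  h <- diff(x)
  R <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    R[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < n - 2) {
      R[i, i + 1] <- h[i + 1] / 6
      R[i + 1, i] <- h[i + 1] / 6
    }
  }
  Q <- matrix(0, n, n - 2)
  for (i in seq_len(n - 2)) {
    Q[i, i] <- 1 / h[i]
    Q[i + 1, i] <- -1 / h[i] - 1 / h[i + 1]
    Q[i + 2, i] <- 1 / h[i + 1]
  }
  K <- Q %*% solve(R) %*% t(Q)
  a <- solve(p * diag(n) + (1 - p) * K, p * y)
  list(fitted = a, gamma = solve(R, t(Q) %*% a))
}

# Optimal 2-cluster partition of the rows of x by exhaustive enumeration,
# minimizing the k-means objective (total within-cluster sum of squared
# distances to centroids). Cluster 1 is the cluster containing row 1.
exhaustive_bipartition <- function(x) {
  n <- nrow(x)
  best <- NULL
  best_obj <- Inf
  for (code in seq_len(2^(n - 1) - 1)) {
    in2 <- as.logical(bitwAnd(code, 2^(seq_len(n - 1) - 1)))
    lab <- c(1L, ifelse(in2, 2L, 1L))
    obj <- 0
    for (cl in 1:2) {
      m <- x[lab == cl, , drop = FALSE]
      ctr <- colMeans(m)
      obj <- obj + sum(sweep(m, 2, ctr)^2)
    }
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- lab
    }
  }
  list(labels = best, objective = best_obj)
}

# k-means objective of a given labeling (for comparing partitions).
partition_objective <- function(x, lab) {
  obj <- 0
  for (cl in unique(lab)) {
    m <- x[lab == cl, , drop = FALSE]
    obj <- obj + sum(sweep(m, 2, colMeans(m))^2)
  }
  obj
}

# Fine-step explicit integrator for the noiseless culture mean model:
# exponential growth while external Pi (at biomass yield) or the internal
# store (a fixed budget of doublings) remains and the carrying capacity is
# not reached. Returns the arrest time.
integrate_culture_arrest <- function(pi0, params, dt = 1e-3) {
  r <- params$max_rate
  od <- params$od_initial
  pi_left <- pi0
  store_gens <- params$internal_store_generations
  t <- 0
  repeat {
    d_od <- od * (2^(r * dt) - 1)
    if (od + d_od > params$stationary_od_cap) return(t)
    if (pi_left > 0) {
      need <- d_od / params$yield_od_per_mM
      if (need <= pi_left) {
        pi_left <- pi_left - need
      } else {
        # split the step between external Pi and the store
        frac_ext <- pi_left / need
        pi_left <- 0
        store_gens <- store_gens - r * dt * (1 - frac_ext)
      }
    } else {
      store_gens <- store_gens - r * dt
      if (store_gens <= 0) return(t)
    }
    od <- od + d_od
    t <- t + dt
    if (t > 200) stop("integrator failed to arrest")
  }
}

# Direct Pearson correlation from the textbook formula (complete pairs).
pearson_direct <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
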