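`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. These deliberately use naive,
# exhaustive formulations so they stay independent of the implementation.

# exhaustive Otsu: try every observed value as threshold, minimize
# intra-class variance; ties broken toward the lower threshold
oracle_otsu <- function(x) {
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]
  best <- Inf
  best_t <- NA_real_
  for (t in cand) {
    lo <- x[x <= t]
    hi <- x[x > t]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best - 1e-9) {
      best <- w
      best_t <- t
    }
  }
  best_t
}

# ordinary least squares through the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# exhaustive grid search for the single-exponential Poisson fit
oracle_grid_decay <- function(t, counts, tau_grid, a_grid, b_grid) {
  best <- Inf
  best_par <- c(NA, NA, NA)
  for (tau in tau_grid) {
    e <- exp(-t / tau)
    for (a in a_grid) {
      for (b in b_grid) {
        mu <- pmax(a * e + b, 1e-12)
        nll <- sum(mu - counts * log(mu))
        if (nll < best) {
          best <- nll
          best_par <- c(a, tau, b)
        }
      }
    }
  }
  list(par = best_par, nll = best)
}

# count 26-connected components of a logical 3D array by flood fill
oracle_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  comp <- 0L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] != 0L) next
    comp <- comp + 1L
    stack <- i
    lab[i] <- comp
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (cur - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (cur - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1L
      x <- rem %% d[1] + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
        j <- xx + (yy - 1L) * d[1] + (zz - 1L) * d[1] * d[2]
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- comp
          stack <- c(stack, j)
        }
      }
    }
  }
  comp
}

default_calib <- function() sv_calibration(tau0_us = 40, kq = 5e-4)

# a detectable-regime flowing capillary (clear dye-exclusion dips);
# any field can be overridden
quick_truth <- function(...) {
  args <- list(flux_rate = 8, rbc_transit_ms = 15, speed_um_ms = 0.4,
               count_rate_plasma = 20, count_rate_rbc = 1, dark_rate = 0.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(capillary_truth, args)
}
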