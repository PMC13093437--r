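# Independent oracles and small fixture builders used across the suite.

# Restricted log-likelihood evaluated the slow, direct way: build the full
# dense covariance matrix V = sigma^2 diag(delta_i^2) + sigma_pop^2 Zp Zp' +
# sigma_fem^2 Zf Zf', compute the GLS coefficients, and plug into
# l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X' V^-1 X| + r' V^-1 r ].
dense_reml_loglik <- function(y, X, pop, fem, sigma, sigma_pop, sigma_fem,
                              delta_obs) {
  n <- length(y)
  p <- ncol(X)
  Zp <- outer(pop, unique(pop), "==") * 1
  Zf <- outer(fem, unique(fem), "==") * 1
  V <- diag((sigma * delta_obs)^2, n) +
    sigma_pop^2 * tcrossprod(Zp) + sigma_fem^2 * tcrossprod(Zf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Maximize the dense criterion directly over log-parameters (brute force).
dense_reml_optimize <- function(y, X, pop, fem, mode_obs, heteroscedastic = TRUE) {
  free_modes <- if (heteroscedastic) setdiff(unique(mode_obs), "mixed") else character(0)
  obj <- function(th) {
    sigma <- exp(th[1]); sp <- exp(th[2]); sf <- exp(th[3])
    delta <- rep(1, length(y))
    for (k in seq_along(free_modes)) {
      delta[mode_obs == free_modes[k]] <- exp(th[3 + k])
    }
    -dense_reml_loglik(y, X, pop, fem, sigma, sp, sf, delta)
  }
  k <- 3 + length(free_modes)
  best <- NULL
  for (s in 1:3) {
    st <- c(log(0.2), log(0.1), log(0.1), rep(0, length(free_modes))) +
      (s - 1) * 0.5
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(loglik = -best$value, par = best$par)
}

# Small deterministic two-population toy for exact model checks. With the
# full fixed design (four female-level columns plus two maternal-mode
# dummies) at least 8 females are needed for the female-level part of X to
# leave the female random effect identifiable.
make_toy_frame <- function(n_pop = 2, fem_per_pop = 4, off_per_fem = 3,
                           seed = 402) {
  withr::local_seed(seed)
  rows <- list()
  modes <- c("mixed", "larviparous", "pueriparous")
  k <- 0
  for (i in seq_len(n_pop)) {
    for (j in seq_len(fem_per_pop)) {
      k <- k + 1
      fid <- sprintf("P%d_F%d", i, j)
      mode <- modes[(k - 1) %% 3 + 1]
      # pure-mode clutches are single-phenotype by definition, so only the
      # mixed clutches can break the stage/mode collinearity: give them a
      # guaranteed asynchronous member plus pure larvae and juveniles
      st <- switch(mode,
        larviparous = list(c("L1", "L"), c("L2", "L")),
        pueriparous = list(c("P1", "P"), c("P2", "P")),
        mixed = list(c("L2", "P"), c("L1", "L"), c("P2", "P"))
      )
      st <- c(st[seq_len(min(off_per_fem, length(st)))],
              st[sample.int(length(st), max(0, off_per_fem - length(st)),
                            replace = TRUE)])
      rows[[fid]] <- data.frame(
        offspring_id = sprintf("%s_O%d", fid, seq_len(off_per_fem)),
        female_id = fid, population = sprintf("P%d", i),
        gill_stage = vapply(st, `[`, "", 1),
        pigment_stage = vapply(st, `[`, "", 2),
        mass_g = NA_real_, total_length_mm = NA_real_,
        logsmi = rnorm(off_per_fem, -1.3, 0.25)
      )
    }
  }
  off <- do.call(rbind, rows)
  n_fem <- length(unique(off$female_id))
  # covariates must not be collinear at the female level (equally spaced
  # svl and clutch size would make nclutch an affine function of fsvl)
  females <- data.frame(
    female_id = unique(off$female_id),
    population = sub("_F.*", "", unique(off$female_id)),
    svl_mm = runif(n_fem, 80, 130),
    clutch_size = sample(4:28, n_fem, replace = TRUE)
  )
  prepare_frame(off, females)
}

# Quick simulated dataset with condition layer for integration-style tests.
make_sim_dataset <- function(seed = 5, ...) {
  sim <- simulate_transect(cline_params(seed = seed, ...))
  simulate_condition(sim, condition_params(), seed = seed + 1)
}
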