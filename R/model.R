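#' @keywords internal
lmm_formula <- ~ fsvl_scaled + fsvl_scaled_sq + nclutch_scaled +
  offspring_stage + fem_mode

# Fixed design shared by the generator and the model frame; factors with a
# single observed level drop out of the design (their effect is not
# estimable) but stay in the frame.
build_design <- function(df) {
  terms <- c("fsvl_scaled", "fsvl_scaled_sq", "nclutch_scaled")
  if (nlevels(df$offspring_stage) > 1) terms <- c(terms, "offspring_stage")
  if (nlevels(df$fem_mode) > 1) terms <- c(terms, "fem_mode")
  stats::model.matrix(stats::reformulate(terms), df)
}

#' Assemble the body-condition model frame
#'
#' Joins offspring condition values to their mothers and builds the fixed
#' design for the logSMI mixed model: z-scored maternal snout-vent length
#' (computed over unique females, sample SD, then broadcast to offspring
#' rows), its square (scale-then-square), z-scored clutch size (total
#' offspring born per female), offspring character stage (reference: larva)
#' and maternal reproductive mode (reference: mixed). Offspring without a
#' logSMI value or without stages are dropped; offspring whose female is
#' absent from the female table are an error.
#'
#' @param offspring Offspring table with `logsmi` (see [add_condition()]),
#'   `female_id`, `population`, `gill_stage`, `pigment_stage`.
#' @param females Female table with `female_id`, `svl_mm`, `clutch_size`.
#' @return Data.frame of class `lmm_frame` with the response, covariates,
#'   factors and grouping columns `pop`, `female`; the model matrix is
#'   attached as attribute `"X"`.
#' @export
prepare_frame <- function(offspring, females) {
  missing_fem <- setdiff(unique(offspring$female_id), females$female_id)
  if (length(missing_fem)) {
    stopf("offspring reference unknown female(s): %s",
          paste(missing_fem, collapse = ", "))
  }
  st <- parse_stage_pair(offspring$gill_stage, offspring$pigment_stage)
  stage <- classify_offspring(st$gill, st$pigment)
  cl <- suppressWarnings(clutch_summaries(offspring))
  fem_mode <- stats::setNames(cl$mode, cl$female_id)[offspring$female_id]
  keep <- !is.na(offspring$logsmi) & !is.na(stage) & !is.na(fem_mode)
  if (!any(keep)) stopf("no offspring with both logsmi and stages")
  off <- offspring[keep, , drop = FALSE]
  stage <- stage[keep]; fem_mode <- fem_mode[keep]
  fem <- females[match(unique(off$female_id), females$female_id), , drop = FALSE]
  if (nrow(fem) < 2) stopf("z-scoring undefined with fewer than 2 females")
  zs <- function(x) {
    s <- stats::sd(x)
    if (s == 0) stopf("cannot z-score a constant female covariate")
    (x - mean(x)) / s
  }
  fsvl <- stats::setNames(zs(fem$svl_mm), fem$female_id)[off$female_id]
  ncl <- stats::setNames(zs(fem$clutch_size), fem$female_id)[off$female_id]
  df <- data.frame(
    logsmi = off$logsmi,
    fsvl_scaled = fsvl,
    fsvl_scaled_sq = fsvl^2,
    nclutch_scaled = ncl,
    offspring_stage = droplevels(factor(as.character(stage),
                                        levels = c("larva", "mixed", "juvenile"))),
    fem_mode = droplevels(factor(fem_mode,
                                 levels = c("mixed", "larviparous", "pueriparous"))),
    pop = factor(off$population),
    female = factor(off$female_id)
  )
  rownames(df) <- NULL
  attr(df, "X") <- build_design(df)
  class(df) <- c("lmm_frame", class(df))
  df
}

# --- profiled REML machinery -------------------------------------------------
#
# V = sigma^2 * W,  W = diag(delta_i^2) + gf^2 Zf Zf' + gp^2 Zp Zp'
# (gf, gp are random-effect SDs relative to the reference residual SD).
# W is block-diagonal by population with female sub-blocks, so W^{-1} U and
# log|W| have closed forms: Sherman-Morrison within each female block, then a
# rank-one population update. Everything is O(n) per evaluation.

lmm_data <- function(frame) {
  X <- attr(frame, "X")
  if (is.null(X)) X <- build_design(frame)
  fem <- frame$female
  ord <- order(frame$pop, fem)  # contiguity not required, but tidy
  list(
    y = frame$logsmi[ord], X = X[ord, , drop = FALSE],
    fem = droplevels(factor(fem[ord])), pop = droplevels(factor(frame$pop[ord])),
    mode = as.character(frame$fem_mode)[ord]
  )
}

# Solve W^{-1} %*% U and log|W| given per-obs delta^2 and relative variances.
wsolve <- function(U, dd, fem, pop, gf2, gp2) {
  n_f <- as.vector(table(fem))
  d_f <- dd[match(levels(fem), fem)]            # delta^2, constant per female
  e_f <- 1 / (d_f + n_f * gf2)
  t_f <- gf2 * e_f
  Sf <- rowsum(U, fem, reorder = TRUE)
  FiU <- (U - t_f[as.integer(fem)] * Sf[as.integer(fem), , drop = FALSE]) /
    dd
  pof <- pop[match(levels(fem), fem)]           # population of each female
  s_p <- as.vector(rowsum(n_f * e_f, pof, reorder = TRUE))
  ldet <- sum(n_f * log(d_f) + log1p(n_f * gf2 / d_f)) + sum(log1p(gp2 * s_p))
  if (gp2 > 0) {
    Sp <- rowsum(FiU, pop, reorder = TRUE)
    shrink <- gp2 / (1 + gp2 * s_p)
    e_obs <- e_f[as.integer(fem)]
    FiU <- FiU - (shrink[as.integer(pop)] * e_obs) *
      Sp[as.integer(pop), , drop = FALSE]
  }
  list(WiU = FiU, logdet = ldet)
}

# Profiled REML objective and (optionally) full GLS components.
reml_core <- function(theta, dat, map, details = FALSE) {
  gp2 <- if (!is.na(map$lsp)) exp(2 * theta[map$lsp]) else 0
  gf2 <- if (!is.na(map$lsf)) exp(2 * theta[map$lsf]) else 0
  delta <- rep(1, length(dat$y))
  if (length(map$ld)) {
    for (k in seq_along(map$ld)) {
      delta[dat$mode == names(map$ld)[k]] <- exp(theta[map$ld[k]])
    }
  }
  U <- cbind(dat$X, dat$y)
  ws <- wsolve(U, delta^2, dat$fem, dat$pop, gf2, gp2)
  p <- ncol(dat$X); n <- length(dat$y)
  M <- crossprod(U, ws$WiU)
  A <- M[seq_len(p), seq_len(p), drop = FALSE]
  b <- M[seq_len(p), p + 1]
  yy <- M[p + 1, p + 1]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(if (details) NULL else 1e10)
  z <- backsolve(R, b, transpose = TRUE)
  rss <- max(yy - sum(z^2), 1e-300)
  sigma2 <- rss / (n - p)
  ldetA <- 2 * sum(log(diag(R)))
  obj <- (n - p) * log(sigma2) + ws$logdet + ldetA
  if (!details) return(obj)
  beta <- backsolve(R, z)
  names(beta) <- colnames(dat$X)
  Ainv <- chol2inv(R)
  list(obj = obj, sigma2 = sigma2, beta = beta,
       vcov_beta = sigma2 * Ainv, gp2 = gp2, gf2 = gf2,
       delta_obs = delta, logdetW = ws$logdet, logdetA = ldetA)
}

#' Fit the heteroscedastic nested mixed model by REML
#'
#' Fits `logsmi ~ fixed effects + (1 | pop / female)` with residual standard
#' deviations allowed to differ by maternal reproductive mode (a
#' varIdent-style variance structure; mixed-mode females are the reference
#' with multiplier 1). The residual scale and fixed effects are profiled out
#' of the restricted likelihood, leaving a smooth objective in the
#' log-relative random-effect SDs and log SD multipliers, maximized by
#' bounded quasi-Newton (L-BFGS-B). On non-convergence the start is jittered
#' deterministically and refit, keeping the best objective. Variance
#' components shrinking to the boundary are reported with a flag, not an
#' error.
#'
#' @param frame An `lmm_frame` from [prepare_frame()].
#' @param heteroscedastic Free residual-SD multipliers by `fem_mode`
#'   (`TRUE`, default) or a single residual SD (`FALSE`).
#' @param random Random intercepts to include: subset of
#'   `c("pop", "female")`.
#' @param control List: `max_restarts` (jittered retries on failure, default
#'   4), `factr` (L-BFGS-B tolerance, default 1e6), `restart_seed`.
#' @return List of class `lmm_fit` with elements `beta` (coefficient table),
#'   `sigma_pop`, `sigma_female`, `sigma_resid`, `delta`, `reml_loglik`,
#'   `fitted`, `residuals` (marginal), `cond_residuals`, `ranef`,
#'   `vcov_beta`, `df_residual`, `convergence`, and the frame.
#' @export
reml_fit <- function(frame, heteroscedastic = TRUE,
                     random = c("pop", "female"), control = list()) {
  ctrl <- utils::modifyList(list(max_restarts = 4, factr = 1e6,
                                 restart_seed = 20260101L), control)
  dat <- lmm_data(frame)
  n <- length(dat$y); p <- ncol(dat$X)
  if (n <= p) stopf("not enough observations (%d) for %d fixed effects", n, p)
  use_pop <- "pop" %in% random && nlevels(dat$pop) > 1
  use_fem <- "female" %in% random && nlevels(dat$fem) > nlevels(dat$pop)
  modes <- unique(dat$mode)
  free_modes <- if (heteroscedastic) setdiff(modes, "mixed") else character(0)
  if (heteroscedastic && !("mixed" %in% modes) && length(free_modes)) {
    # reference absent: anchor the first observed mode instead
    free_modes <- free_modes[-1]
  }
  map <- list(lsp = NA_integer_, lsf = NA_integer_, ld = integer(0))
  k <- 0L
  if (use_pop) { k <- k + 1L; map$lsp <- k }
  if (use_fem) { k <- k + 1L; map$lsf <- k }
  if (length(free_modes)) {
    map$ld <- stats::setNames(k + seq_along(free_modes), free_modes)
    k <- k + length(free_modes)
  }
  start <- rep(0, k)
  if (!is.na(map$lsp)) start[map$lsp] <- log(0.5)
  if (!is.na(map$lsf)) start[map$lsf] <- log(0.5)
  lower <- rep(-4.6, k); upper <- rep(4.6, k)
  if (!is.na(map$lsp)) { lower[map$lsp] <- -13.8; upper[map$lsp] <- 7 }
  if (!is.na(map$lsf)) { lower[map$lsf] <- -13.8; upper[map$lsf] <- 7 }

  best <- NULL
  attempts <- 0L
  if (k > 0) {
    repeat {
      th0 <- if (attempts == 0) start else
        with_seed(ctrl$restart_seed + attempts,
                  pmin(pmax(start + stats::rnorm(k, 0, 1), lower), upper))
      opt <- stats::optim(th0, reml_core, dat = dat, map = map,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(factr = ctrl$factr, maxit = 500))
      if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
      attempts <- attempts + 1L
      if ((opt$convergence == 0 && is.finite(opt$value)) ||
          attempts > ctrl$max_restarts) break
    }
    if (best$convergence != 0 && !is.finite(best$value)) {
      stopf("REML optimization failed after %d attempts", attempts)
    }
    theta <- best$par
  } else {
    theta <- numeric(0)
    best <- list(value = reml_core(theta, dat, map), convergence = 0L)
  }
  fin <- reml_core(theta, dat, map, details = TRUE)
  if (is.null(fin)) stopf("design matrix singular at the optimum")
  sigma <- sqrt(fin$sigma2)
  delta <- stats::setNames(rep(1, length(modes)), modes)
  if (length(map$ld)) delta[names(map$ld)] <- exp(theta[map$ld])
  delta <- delta[order(match(names(delta), reproductive_modes()))]

  # numeric gradient at the optimum (central differences)
  grad <- if (k > 0) vapply(seq_len(k), function(j) {
    h <- 1e-5; tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (reml_core(tp, dat, map) - reml_core(tm, dat, map)) / (2 * h)
  }, numeric(1)) else numeric(0)
  at_boundary <- k > 0 && any(abs(theta - lower) < 1e-6 | abs(theta - upper) < 1e-6)

  fitted_fix <- drop(dat$X %*% fin$beta)
  r <- dat$y - fitted_fix
  wr <- wsolve(cbind(r), fin$delta_obs^2, dat$fem, dat$pop, fin$gf2, fin$gp2)$WiU
  u_fem <- if (use_fem) fin$gf2 * drop(rowsum(wr, dat$fem)) else
    stats::setNames(rep(0, nlevels(dat$fem)), levels(dat$fem))
  u_pop <- if (use_pop) fin$gp2 * drop(rowsum(wr, dat$pop)) else
    stats::setNames(rep(0, nlevels(dat$pop)), levels(dat$pop))
  names(u_fem) <- levels(dat$fem); names(u_pop) <- levels(dat$pop)
  cond_resid <- r - u_pop[as.integer(dat$pop)] - u_fem[as.integer(dat$fem)]

  beta_se <- sqrt(diag(fin$vcov_beta))
  loglik <- -0.5 * ((n - p) * (log(2 * pi) + 1) + fin$obj)
  structure(list(
    beta = data.frame(estimate = fin$beta, se = beta_se,
                      t = fin$beta / beta_se, row.names = names(fin$beta)),
    sigma_pop = sigma * sqrt(fin$gp2),
    sigma_female = sigma * sqrt(fin$gf2),
    sigma_resid = sigma,
    delta = delta,
    reml_loglik = loglik,
    fitted = fitted_fix,
    residuals = r,
    cond_residuals = cond_resid,
    delta_obs = fin$delta_obs,
    ranef = list(pop = u_pop, female = u_fem),
    vcov_beta = fin$vcov_beta,
    df_residual = n - p,
    n = n, p = p,
    mode_obs = dat$mode,
    frame = frame,
    heteroscedastic = heteroscedastic,
    random = intersect(random, c(if (use_pop) "pop", if (use_fem) "female")),
    convergence = list(code = best$convergence, objective = fin$obj,
                       attempts = attempts, max_abs_grad = max(abs(grad), 0),
                       at_boundary = at_boundary)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Heteroscedastic nested mixed model (REML)\n")
  cat(sprintf("  observations: %d   REML log-likelihood: %.4f\n",
              x$n, x$reml_loglik))
  cat(sprintf("  random-intercept SDs: pop %.4f, female %.4f; residual SD %.4f\n",
              x$sigma_pop, x$sigma_female, x$sigma_resid))
  cat("  residual SD multipliers by maternal mode:\n")
  print(round(x$delta, 4))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Estimated marginal means with Tukey-adjusted contrasts
#'
#' EMMs predict each level of the chosen factor at covariates fixed to zero
#' (their means, by construction of the z-scoring) with the other factor
#' averaged with equal weights over its levels. Contrast standard errors come
#' from the fixed-effect covariance; pairwise p-values use the studentized
#' range distribution with `k` = number of levels and residual degrees of
#' freedom `n - rank(X)` (with `k = 2` the adjustment equals the unadjusted
#' two-sided t-test).
#'
#' @param fit An `lmm_fit`.
#' @param factor `"fem_mode"` or `"offspring_stage"`.
#' @return List of class `emm_result` with `emmeans` and `contrasts`
#'   data.frames, `factor`, `df`.
#' @export
emmeans_tukey <- function(fit, factor = c("fem_mode", "offspring_stage")) {
  factor <- match.arg(factor)
  frame <- fit$frame
  lev <- levels(frame[[factor]])
  if (length(lev) < 2) stopf("factor %s has a single observed level", factor)
  other <- setdiff(c("fem_mode", "offspring_stage"), factor)
  lev_o <- levels(frame[[other]])
  cn <- rownames(fit$beta)
  grid <- matrix(0, nrow = length(lev), ncol = length(cn),
                 dimnames = list(lev, cn))
  grid[, "(Intercept)"] <- 1
  for (l in lev) {
    col <- paste0(factor, l)
    if (col %in% cn) grid[l, col] <- 1
  }
  for (lo in lev_o) {
    col <- paste0(other, lo)
    if (col %in% cn) grid[, col] <- 1 / length(lev_o)
  }
  est <- drop(grid %*% fit$beta$estimate)
  se <- sqrt(diag(grid %*% fit$vcov_beta %*% t(grid)))
  emm <- data.frame(level = lev, emmean = est, se = se)
  pairs <- utils::combn(seq_along(lev), 2)
  k <- length(lev); df <- fit$df_residual
  ctr <- apply(pairs, 2, function(ij) {
    cvec <- grid[ij[1], ] - grid[ij[2], ]
    d <- sum(cvec * fit$beta$estimate)
    s <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
    tval <- d / s
    data.frame(contrast = paste(lev[ij[1]], "-", lev[ij[2]]),
               estimate = d, se = s, t = tval, df = df,
               p_unadjusted = 2 * stats::pt(-abs(tval), df),
               p_tukey = stats::ptukey(sqrt(2) * abs(tval), k, df,
                                       lower.tail = FALSE))
  })
  structure(list(emmeans = emm, contrasts = do.call(rbind, ctr),
                 factor = factor, df = df),
            class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat(sprintf("Estimated marginal means for %s (df = %d)\n", x$factor, x$df))
  print(transform(x$emmeans, emmean = round(emmean, 4), se = round(se, 4)))
  cat("Pairwise contrasts (Tukey-adjusted):\n")
  print(transform(x$contrasts, estimate = round(estimate, 4),
                  se = round(se, 4), t = round(t, 3),
                  p_unadjusted = signif(p_unadjusted, 3),
                  p_tukey = signif(p_tukey, 3)))
  invisible(x)
}

#' Variance decomposition: ICC and marginal/conditional R-squared
#'
#' Under the heteroscedastic residual structure the single "residual
#' variance" entering these summaries is the observation-weighted mean of the
#' mode-specific residual variances. The adjusted ICC is the random-intercept
#' share of (random + residual) variance; marginal R2 is the fixed-effect
#' share of total variance and conditional R2 adds the random intercepts.
#'
#' @param fit An `lmm_fit`.
#' @return List with `icc_adjusted`, `r2_marginal`, `r2_conditional`,
#'   `var_fixed`, `var_pop`, `var_female`, `var_resid_mean`.
#' @export
variance_summary <- function(fit) {
  s2p <- fit$sigma_pop^2; s2f <- fit$sigma_female^2
  wbar <- mean((fit$sigma_resid * fit$delta_obs)^2)
  vfix <- stats::var(fit$fitted)
  tot <- vfix + s2p + s2f + wbar
  list(
    icc_adjusted = (s2p + s2f) / (s2p + s2f + wbar),
    r2_marginal = vfix / tot,
    r2_conditional = (vfix + s2p + s2f) / tot,
    var_fixed = vfix, var_pop = s2p, var_female = s2f, var_resid_mean = wbar
  )
}

#' Residual and random-effect diagnostics
#'
#' Standardized (conditional) residuals divided by their mode-specific SD
#' should have unit spread in every maternal-mode group when the variance
#' structure is right; their correlation with fitted values and with normal
#' quantiles probe trend and distributional misfit, and the same quantile
#' correlation is reported for the predicted female intercepts.
#'
#' @param fit An `lmm_fit`.
#' @return List with `std_residuals`, `per_mode_sd` (data.frame),
#'   `resid_fitted_cor`, `qq_cor_residuals`, `qq_cor_ranef_female`.
#' @export
lmm_diagnostics <- function(fit) {
  std <- fit$cond_residuals / (fit$sigma_resid * fit$delta_obs)
  per_mode <- do.call(rbind, lapply(sort(unique(fit$mode_obs)), function(m) {
    idx <- fit$mode_obs == m
    data.frame(fem_mode = m, n = sum(idx),
               raw_resid_sd = stats::sd(fit$cond_residuals[idx]),
               std_resid_sd = stats::sd(std[idx]))
  }))
  qqc <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(sort(v), stats::qnorm(stats::ppoints(length(v))))
  }
  list(
    std_residuals = std,
    per_mode_sd = per_mode,
    resid_fitted_cor = if (stats::sd(fit$fitted) > 0 && stats::sd(std) > 0)
      stats::cor(fit$fitted, std) else NA_real_,
    qq_cor_residuals = qqc(std),
    qq_cor_ranef_female = qqc(fit$ranef$female)
  )
}
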