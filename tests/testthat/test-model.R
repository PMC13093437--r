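test_that("frame preparation z-scores at the female level with fixed references", {
  off <- data.frame(
    offspring_id = paste0("o", 1:6),
    female_id = rep(c("f1", "f2", "f3"), each = 2),
    population = rep(c("A", "A", "B"), each = 2),
    gill_stage = c("L1", "L1", "L2", "L2", "P1", "P2"),
    pigment_stage = c("L", "L", "LP", "LP", "P", "P"),
    logsmi = seq(-1.5, -1, length.out = 6)
  )
  fem <- data.frame(female_id = c("f1", "f2", "f3"),
                    population = c("A", "A", "B"),
                    svl_mm = c(80, 100, 120), clutch_size = c(10, 20, 30))
  fr <- prepare_frame(off, fem)
  # one z-score value per female, sample-SD convention
  expect_equal(unique(fr$fsvl_scaled), c(-1, 0, 1))
  expect_equal(fr$fsvl_scaled_sq, fr$fsvl_scaled^2)
  expect_equal(levels(fr$fem_mode)[1], "mixed")
  expect_equal(levels(fr$offspring_stage)[1], "larva")
  # unlinked offspring named in the error
  off_bad <- off; off_bad$female_id[1] <- "ghost"
  expect_error(prepare_frame(off_bad, fem), "ghost")
  # single female: scaling undefined
  expect_error(prepare_frame(off[1:2, ], fem[1, , drop = FALSE]),
               "fewer than 2 females")
})

test_that("REML log-likelihood matches the dense-covariance oracle on toys", {
  for (seed in c(402, 403, 404)) {
    fr <- make_toy_frame(seed = seed)  # 24 observations, 8 females
    fit <- reml_fit(fr)
    dat <- list(y = fr$logsmi, X = attr(fr, "X"),
                pop = as.character(fr$pop), fem = as.character(fr$female))
    delta_obs <- fit$delta[as.character(fr$fem_mode)]
    oracle <- dense_reml_loglik(dat$y, dat$X, dat$pop, dat$fem,
                                fit$sigma_resid, fit$sigma_pop,
                                fit$sigma_female, unname(delta_obs))
    expect_equal(fit$reml_loglik, oracle, tolerance = 1e-8)
  }
})

test_that("REML optimum matches brute-force maximization of the dense criterion", {
  fr <- make_toy_frame(n_pop = 2, fem_per_pop = 4, off_per_fem = 3, seed = 90)
  fit <- reml_fit(fr)
  oracle <- dense_reml_optimize(fr$logsmi, attr(fr, "X"),
                                as.character(fr$pop), as.character(fr$female),
                                as.character(fr$fem_mode))
  expect_equal(fit$reml_loglik, oracle$loglik, tolerance = 1e-5)
  expect_gte(fit$reml_loglik, oracle$loglik - 1e-6)
})

test_that("the model collapses to ordinary least squares without random structure", {
  withr::local_seed(88)
  n <- 60
  off <- data.frame(
    offspring_id = paste0("o", 1:n),
    female_id = rep(paste0("f", 1:6), length.out = n),
    population = "P1",
    gill_stage = rep(c("L1", "L2", "P1"), each = 20),
    pigment_stage = rep(c("L", "LP", "P"), each = 20),
    logsmi = rnorm(n, -1.3, 0.2)
  )
  fem <- data.frame(female_id = paste0("f", 1:6), population = "P1",
                    svl_mm = seq(80, 130, 10), clutch_size = c(8, 12, 20, 9, 15, 25))
  fr <- prepare_frame(off, fem)
  fit <- reml_fit(fr, heteroscedastic = FALSE, random = character(0))
  ols <- lm.fit(attr(fr, "X"), fr$logsmi)
  expect_equal(fit$beta$estimate, unname(ols$coefficients), tolerance = 1e-6)
  expect_equal(fit$sigma_pop, 0)
  expect_equal(fit$sigma_female, 0)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  sim <- make_sim_dataset(seed = 42)
  off <- add_condition(sim$offspring)
  fr <- prepare_frame(off, sim$females)
  fit <- reml_fit(fr)
  d <- as.data.frame(fr)
  ref <- nlme::lme(
    logsmi ~ fsvl_scaled + fsvl_scaled_sq + nclutch_scaled +
      offspring_stage + fem_mode,
    random = ~ 1 | pop / female,
    weights = nlme::varIdent(form = ~ 1 | fem_mode),
    data = d, method = "REML",
    control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit$beta$estimate, unname(nlme::fixef(ref)), tolerance = 1e-4)
  vc <- nlme::VarCorr(ref)
  # the random-effect SDs are weakly curved directions of the objective, so
  # two independent optimizers agree only to ~1%
  expect_equal(fit$sigma_pop, as.numeric(vc[2, 2]), tolerance = 0.01)
  expect_equal(fit$sigma_female, as.numeric(vc[4, 2]), tolerance = 0.01)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  # nlme parameterizes varIdent against its own reference; compare ratios
  w <- stats::coef(ref$modelStruct$varStruct, unconstrained = FALSE)
  ref_delta <- c(1, w) / w[["mixed"]]
  names(ref_delta)[1] <- setdiff(levels(d$fem_mode), names(w))[1]
  for (m in names(fit$delta)) {
    expect_equal(unname(fit$delta[m]), unname(ref_delta[m]), tolerance = 1e-3)
  }
})

test_that("freeing the variance multipliers never lowers the restricted likelihood", {
  for (s in c(5, 23)) {
    sim <- make_sim_dataset(seed = s)
    fr <- prepare_frame(add_condition(sim$offspring), sim$females)
    free <- reml_fit(fr, heteroscedastic = TRUE)
    fixed <- reml_fit(fr, heteroscedastic = FALSE)
    expect_gte(free$reml_loglik, fixed$reml_loglik - 1e-8)
  }
})

test_that("EMMs equal group means in a balanced one-way layout without random effects", {
  withr::local_seed(12)
  n_per <- 30
  stages <- rep(c("L1", "L2", "P2"), each = n_per)
  pigs <- rep(c("L", "LP", "P"), each = n_per)  # larva / mixed / juvenile
  mu <- rep(c(-1.5, -1.2, -1.3), each = n_per)
  off <- data.frame(
    offspring_id = paste0("o", seq_along(stages)),
    female_id = rep(paste0("f", 1:6), length.out = length(stages)),
    population = "P1",
    gill_stage = stages, pigment_stage = pigs,
    logsmi = mu + rnorm(length(stages), 0, 0.05)
  )
  # make every clutch mixed so fem_mode has one level and drops out
  fem <- data.frame(female_id = paste0("f", 1:6), population = "P1",
                    svl_mm = 80:85, clutch_size = 10:15)
  fr <- prepare_frame(off, fem)
  # restrict the design to the stage factor alone
  attr(fr, "X") <- stats::model.matrix(~ offspring_stage, fr)
  fit <- reml_fit(fr, heteroscedastic = FALSE, random = character(0))
  emm <- emmeans_tukey(fit, "offspring_stage")
  grp <- tapply(fr$logsmi, fr$offspring_stage, mean)
  expect_equal(emm$emmeans$emmean, as.numeric(grp[emm$emmeans$level]),
               tolerance = 1e-8)
})

test_that("Tukey adjustment with two levels equals the unadjusted p-value", {
  fr <- make_toy_frame(n_pop = 2, fem_per_pop = 4, off_per_fem = 4, seed = 7)
  # collapse to two maternal modes by relabelling pueriparous as larviparous
  fr2 <- fr
  fr2$fem_mode <- droplevels(factor(ifelse(fr2$fem_mode == "pueriparous",
                                           "larviparous",
                                           as.character(fr2$fem_mode)),
                                    levels = c("mixed", "larviparous")))
  attr(fr2, "X") <- reproclines:::build_design(fr2)
  fit <- reml_fit(fr2)
  emm <- emmeans_tukey(fit, "fem_mode")
  expect_equal(emm$contrasts$p_tukey, emm$contrasts$p_unadjusted,
               tolerance = 1e-10)
  # with three levels the adjusted p is never smaller
  fit3 <- reml_fit(fr)
  emm3 <- emmeans_tukey(fit3, "fem_mode")
  expect_true(all(emm3$contrasts$p_tukey >= emm3$contrasts$p_unadjusted - 1e-12))
})

test_that("EMM contrasts agree with the emmeans package on an nlme fit", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("emmeans")
  sim <- make_sim_dataset(seed = 42)
  fr <- prepare_frame(add_condition(sim$offspring), sim$females)
  fit <- reml_fit(fr)
  mine <- emmeans_tukey(fit, "fem_mode")
  d <- as.data.frame(fr)
  ref <- nlme::lme(
    logsmi ~ fsvl_scaled + fsvl_scaled_sq + nclutch_scaled +
      offspring_stage + fem_mode,
    random = ~ 1 | pop / female,
    weights = nlme::varIdent(form = ~ 1 | fem_mode),
    data = d, method = "REML", control = nlme::lmeControl(opt = "optim"))
  eref <- summary(emmeans::emmeans(
    ref, "fem_mode",
    at = list(fsvl_scaled = 0, fsvl_scaled_sq = 0, nclutch_scaled = 0),
    weights = "equal", mode = "containment"))
  ord <- match(mine$emmeans$level, as.character(eref$fem_mode))
  expect_equal(mine$emmeans$emmean, eref$emmean[ord], tolerance = 1e-3)
  expect_equal(mine$emmeans$se, eref$SE[ord], tolerance = 0.02)
})

test_that("variance summary obeys its structural identities", {
  fr <- make_toy_frame(n_pop = 3, fem_per_pop = 3, off_per_fem = 5, seed = 61)
  fit <- reml_fit(fr)
  vs <- variance_summary(fit)
  expect_true(vs$r2_marginal <= vs$r2_conditional)
  expect_true(vs$r2_conditional <= 1 && vs$icc_adjusted >= 0 &&
                vs$icc_adjusted <= 1)
  # without random structure the ICC is zero and the two R2 coincide
  fit0 <- reml_fit(fr, random = character(0))
  vs0 <- variance_summary(fit0)
  expect_equal(vs0$icc_adjusted, 0)
  expect_equal(vs0$r2_marginal, vs0$r2_conditional)
})

test_that("diagnostics expose variance-structure misspecification", {
  # generator with strong heteroscedasticity, fit forced homoscedastic:
  # raw residual SDs should differ by roughly the delta ratio across modes
  cp <- condition_params(delta = c(larviparous = 2, mixed = 1,
                                   pueriparous = 0.5))
  sim <- simulate_transect(cline_params(females_per_population = 12, seed = 31))
  sim <- simulate_condition(sim, cp, seed = 31)
  off <- sim$offspring
  off$logsmi <- attr(off, "truth")$logsmi
  off$smi <- exp(off$logsmi)
  fr <- prepare_frame(off, sim$females)
  fit <- reml_fit(fr, heteroscedastic = FALSE)
  dg <- lmm_diagnostics(fit)
  sds <- setNames(dg$per_mode_sd$raw_resid_sd, dg$per_mode_sd$fem_mode)
  expect_gt(sds[["larviparous"]] / sds[["pueriparous"]], 2.5)
  # correctly specified fit standardizes every mode to unit spread
  fit2 <- reml_fit(fr, heteroscedastic = TRUE)
  dg2 <- lmm_diagnostics(fit2)
  expect_true(all(abs(dg2$per_mode_sd$std_resid_sd - 1) < 0.12))
})
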