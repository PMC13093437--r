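#' Logistic cline propensity
#'
#' The probability-like propensity for the derived (pueriparous) reproductive
#' mode at transect position `x`: `q = 1 / (1 + exp(-(x - c) / w))`. `c` is
#' the cline centre and `w` its width scale in km; the curve rises from 0 to
#' 1 with increasing `x`. Positions in this package are measured from the
#' southern terminus, so the propensity increases northwards, matching a
#' contact zone with a pueriparous lineage in the north and a larviparous
#' lineage in the south.
#'
#' @param x Position(s) along the transect, km.
#' @param c Cline centre, km.
#' @param w Cline width scale, km; must be positive.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' cline_propensity(50, 50, 10)            # 0.5 at the centre
#' cline_propensity(50 + 10 * log(3), 50, 10)  # 0.75
cline_propensity <- function(x, c, w) {
  if (!is.numeric(w) || any(w <= 0)) stopf("cline width w must be positive")
  stats::plogis((x - c) / w)
}

#' Transect simulation parameters
#'
#' Bundles the knobs of the synthetic hybrid-zone generator. Defaults emulate
#' the sampled contact zone: 12 populations evenly spaced along a 105.5 km
#' transect, a logistic mode cline centred mid-transect, larger clutches in
#' the larviparous lineage, ordered developmental-stage thresholds on a
#' latent progress scale, and strong gill-pigmentation coupling.
#'
#' @param n_populations Number of populations along the transect.
#' @param positions Km from the southern terminus; default evenly spaced over
#'   105.5 km.
#' @param center,width Logistic cline centre and width scale, km.
#' @param females_per_population Females with recorded births per population.
#' @param clutch_size_means Expected clutch sizes `(larviparous, pueriparous)`;
#'   sizes are truncated-at-1 Poisson, capped at 30.
#' @param stage_thresholds_gill Three increasing cut points in (0,1) binning
#'   latent developmental progress into gill stages L1/L2/P1/P2.
#' @param stage_thresholds_pigment Two increasing cut points binning pigment
#'   progress into L/LP/P.
#' @param stage_coupling Weight `rho` in `[0,1]` tying pigment progress to
#'   gill progress; 1 = fully synchronous characters.
#' @param asynchrony_scale Multiplier on the propensity-dependent spread
#'   `a(1-a)` of per-offspring developmental noise (maximal mid-cline).
#' @param propensity_concentration Beta concentration of the female-level
#'   pueriparity propensity around the population cline value.
#' @param svl_base,svl_span,svl_sd Female snout-vent length model, mm: mean
#'   `svl_base - svl_span * a` (the larviparous lineage is larger) plus
#'   Gaussian noise.
#' @param seed Integer seed; identical parameters give byte-identical tables.
#' @return List of class `cline_params`.
#' @export
cline_params <- function(n_populations = 12,
                         positions = NULL,
                         center = 52.75,
                         width = 12,
                         females_per_population = 5,
                         clutch_size_means = c(larviparous = 20, pueriparous = 8),
                         stage_thresholds_gill = c(0.25, 0.5, 0.75),
                         stage_thresholds_pigment = c(1 / 3, 2 / 3),
                         stage_coupling = 0.9,
                         asynchrony_scale = 0.5,
                         propensity_concentration = 8,
                         svl_base = 110, svl_span = 25, svl_sd = 8,
                         seed = 1L) {
  if (is.null(positions)) {
    positions <- seq(0, 105.5, length.out = n_populations)
  }
  stopifnot(length(positions) == n_populations)
  if (width <= 0) stopf("cline width must be positive")
  if (is.unsorted(stage_thresholds_gill, strictly = TRUE) ||
      any(stage_thresholds_gill <= 0) || any(stage_thresholds_gill >= 1)) {
    stopf("gill thresholds must be strictly increasing within (0,1)")
  }
  if (is.unsorted(stage_thresholds_pigment, strictly = TRUE) ||
      any(stage_thresholds_pigment <= 0) || any(stage_thresholds_pigment >= 1)) {
    stopf("pigment thresholds must be strictly increasing within (0,1)")
  }
  if (stage_coupling < 0 || stage_coupling > 1) stopf("stage_coupling must be in [0,1]")
  if (asynchrony_scale < 0) stopf("asynchrony_scale must be >= 0")
  structure(list(
    n_populations = n_populations, positions = positions,
    center = center, width = width,
    females_per_population = females_per_population,
    clutch_size_means = clutch_size_means,
    stage_thresholds_gill = stage_thresholds_gill,
    stage_thresholds_pigment = stage_thresholds_pigment,
    stage_coupling = stage_coupling,
    asynchrony_scale = asynchrony_scale,
    propensity_concentration = propensity_concentration,
    svl_base = svl_base, svl_span = svl_span, svl_sd = svl_sd,
    seed = as.integer(seed)
  ), class = "cline_params")
}

# Beta draw with mean m and concentration kappa, guarded near the endpoints.
rbeta_mean <- function(n, m, kappa) {
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  stats::rbeta(n, m * kappa, (1 - m) * kappa)
}

# Truncated-at-1 Poisson via inverse CDF, capped at 30 offspring.
rtpois1 <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  pmin(stats::qpois(u, lambda), 30L)
}

bin_progress <- function(d, thresholds, labels) {
  labels[findInterval(d, thresholds) + 1L]
}

#' Simulate a hybrid-zone transect of females and staged offspring
#'
#' Generates female and offspring tables with the structure the downstream
#' analysis assumes. For each female: a pueriparity propensity `a` drawn from
#' a Beta distribution centred on the population's logistic cline value; a
#' truncated-at-1 Poisson clutch size whose mean interpolates between the
#' larviparous and pueriparous expectations; per-offspring latent
#' developmental progress `d = clip(a + eps)` with noise SD
#' `asynchrony_scale * a * (1 - a)` (maximal mid-cline, the signature of
#' heterochronic mixing), binned into gill stages; pigment progress
#' `rho * d + (1 - rho) * uniform`, binned into pigmentation stages; and a
#' snout-vent length decreasing with `a` (the larviparous lineage is the
#' larger one). Morphometrics are left missing until [simulate_condition()].
#'
#' All draws flow through per-unit substreams keyed by stable identifier
#' hashes, so the same seed gives byte-identical tables regardless of row
#' order, and different seeds decorrelate everything.
#'
#' @param params A [cline_params()] object.
#' @return List with elements `females` (population, female_id,
#'   transect_position_km, svl_mm, clutch_size, puer_propensity), `offspring`
#'   (offspring_id, female_id, population, gill_stage, pigment_stage, mass_g,
#'   total_length_mm), and `populations` (metadata table).
#' @export
simulate_transect <- function(params = cline_params()) {
  stopifnot(inherits(params, "cline_params"))
  p <- params
  pops <- sprintf("POP%02d", seq_len(p$n_populations))
  q <- cline_propensity(p$positions, p$center, p$width)
  fem_rows <- list(); off_rows <- list()
  for (i in seq_len(p$n_populations)) {
    for (j in seq_len(p$females_per_population)) {
      fid <- sprintf("%s_F%02d", pops[i], j)
      with_seed(substream_seed(p$seed, fid), {
        a <- rbeta_mean(1, q[i], p$propensity_concentration)
        lambda <- p$clutch_size_means[[1]] +
          (p$clutch_size_means[[2]] - p$clutch_size_means[[1]]) * a
        size <- rtpois1(1, lambda)
        svl <- stats::rnorm(1, p$svl_base - p$svl_span * a, p$svl_sd)
        d <- pmin(pmax(a + stats::rnorm(size, 0, p$asynchrony_scale * a * (1 - a)),
                       0), 1 - 1e-12)
        gill <- bin_progress(d, p$stage_thresholds_gill, gill_stages())
        dp <- p$stage_coupling * d + (1 - p$stage_coupling) * stats::runif(size)
        pig <- bin_progress(pmin(dp, 1 - 1e-12), p$stage_thresholds_pigment,
                            pigment_stages())
        fem_rows[[fid]] <- data.frame(
          population = pops[i], female_id = fid,
          transect_position_km = p$positions[i],
          svl_mm = svl, clutch_size = size, puer_propensity = a
        )
        off_rows[[fid]] <- data.frame(
          offspring_id = sprintf("%s_O%02d", fid, seq_len(size)),
          female_id = fid, population = pops[i],
          gill_stage = gill, pigment_stage = pig,
          mass_g = NA_real_, total_length_mm = NA_real_
        )
      })
    }
  }
  females <- do.call(rbind, fem_rows)
  offspring <- do.call(rbind, off_rows)
  rownames(females) <- rownames(offspring) <- NULL
  populations <- data.frame(
    population = pops, transect_position_km = p$positions,
    n_females_collected = p$females_per_population,
    field_mode = NA_character_
  )
  list(females = females, offspring = offspring, populations = populations,
       params = p)
}

#' Body-condition simulation parameters
#'
#' Parameters of the log Scaled Mass Index (logSMI) generating model layered
#' on a staged transect: fixed effects on the logSMI scale, nested
#' population/female random-intercept SDs, a reference residual SD, and
#' residual-SD multipliers by maternal reproductive mode (mixed-mode females
#' are the reference, multiplier 1). The variance defaults take the fitted
#' magnitudes reported for this system — population SD 0.088, female SD
#' 0.095, residual SD 0.208, and multipliers 1.10 (larviparous), 1.00
#' (mixed), 0.65 (pueriparous) — as the realistic scenario.
#'
#' @param beta Named fixed-effect coefficients on the logSMI scale, in the
#'   design order used by [prepare_frame()]: intercept, scaled maternal SVL,
#'   its square, scaled clutch size, offspring-stage contrasts (mixed,
#'   juvenile vs larva), maternal-mode contrasts (larviparous, pueriparous vs
#'   mixed).
#' @param sigma_pop,sigma_female Random-intercept SDs.
#' @param sigma_resid Residual SD of the reference (mixed-mode) group.
#' @param delta Residual-SD multipliers named by maternal mode; mixed is 1.
#' @param length_means Mean total length (mm) of newborns by offspring
#'   phenotype (larva, mixed, juvenile).
#' @param length_sd Within-phenotype total-length SD, mm.
#' @param l0_target Reference length (mm) at which logSMI is expressed.
#' @param b_true Allometric slope used to invert the SMI transform.
#' @param prop_missing Fraction of newborns with unmeasurable morphometrics
#'   (mass, length, or both set missing), emulating degraded individuals the
#'   field protocol cannot measure.
#' @return List of class `condition_params`.
#' @export
condition_params <- function(beta = c("(Intercept)" = log(0.28),
                                      fsvl_scaled = 0,
                                      fsvl_scaled_sq = -0.01,
                                      nclutch_scaled = -0.025,
                                      offspring_stagemixed = 0.01,
                                      offspring_stagejuvenile = 0.01,
                                      fem_modelarviparous = -0.04,
                                      fem_modepueriparous = -0.015),
                             sigma_pop = 0.088,
                             sigma_female = 0.095,
                             sigma_resid = 0.208,
                             delta = c(larviparous = 1.10, mixed = 1,
                                       pueriparous = 0.65),
                             length_means = c(larva = 28, mixed = 40,
                                              juvenile = 52),
                             length_sd = 6,
                             l0_target = 40,
                             b_true = 3,
                             prop_missing = 0.075) {
  if (any(c(sigma_pop, sigma_female, sigma_resid) < 0)) {
    stopf("SDs must be non-negative")
  }
  if (any(delta <= 0) || abs(delta[["mixed"]] - 1) > 1e-12) {
    stopf("delta must be strictly positive with delta['mixed'] = 1")
  }
  if (prop_missing < 0 || prop_missing >= 1) {
    stopf("prop_missing must be in [0, 1)")
  }
  structure(list(beta = beta, sigma_pop = sigma_pop,
                 sigma_female = sigma_female, sigma_resid = sigma_resid,
                 delta = delta, length_means = length_means,
                 length_sd = length_sd, l0_target = l0_target,
                 b_true = b_true, prop_missing = prop_missing),
            class = "condition_params")
}

#' Fill simulated morphometrics from a logSMI generating model
#'
#' Draws population and female random intercepts, builds the fixed-effect
#' design exactly as [prepare_frame()] would (female-level z-scoring,
#' reference levels mixed / larva), simulates
#' `logsmi = X beta + u_pop + u_female + eps` with
#' `sd(eps) = sigma_resid * delta[mode]`, then inverts the Scaled Mass Index
#' transform: total length is drawn around a phenotype-dependent mean and
#' `mass = exp(logsmi) * (length / l0_target)^b_true`, so the downstream SMI
#' computation recovers the generated logSMI up to allometry-estimation
#' error.
#'
#' @param sim Output of [simulate_transect()].
#' @param params A [condition_params()] object.
#' @param seed Integer seed for the condition layer (independent of the
#'   transect seed).
#' @return `sim` with `mass_g` and `total_length_mm` filled; the generating
#'   truth (design, coefficients, random effects, true logSMI) is attached as
#'   attribute `"truth"` for calibration studies.
#' @export
simulate_condition <- function(sim, params = condition_params(), seed = 1L) {
  stopifnot(inherits(params, "condition_params"))
  off <- sim$offspring
  fem <- sim$females
  st <- parse_stage_pair(off$gill_stage, off$pigment_stage)
  stage <- classify_offspring(st$gill, st$pigment)
  cl <- clutch_summaries(off)
  fem_mode <- stats::setNames(cl$mode, cl$female_id)[off$female_id]
  X <- condition_design(off, fem, stage, fem_mode)
  beta <- params$beta[colnames(X)]
  if (anyNA(beta)) stopf("beta is missing coefficients for: %s",
                         paste(colnames(X)[is.na(beta)], collapse = ", "))
  pops <- sort(unique(off$population))
  u_pop <- stats::setNames(vapply(pops, function(pp) {
    with_seed(substream_seed(seed, paste0("pop:", pp)),
              stats::rnorm(1, 0, params$sigma_pop))
  }, numeric(1)), pops)
  fems <- fem$female_id
  u_fem <- stats::setNames(vapply(fems, function(ff) {
    with_seed(substream_seed(seed, paste0("fem:", ff)),
              stats::rnorm(1, 0, params$sigma_female))
  }, numeric(1)), fems)
  resid_sd <- params$sigma_resid * params$delta[fem_mode]
  eps <- numeric(nrow(off)); len <- numeric(nrow(off))
  for (ff in fems) {
    idx <- which(off$female_id == ff)
    with_seed(substream_seed(seed, paste0("obs:", ff)), {
      eps[idx] <- stats::rnorm(length(idx), 0, resid_sd[idx])
      len[idx] <- pmax(stats::rnorm(length(idx),
                                    params$length_means[as.character(stage[idx])],
                                    params$length_sd), 10)
    })
  }
  logsmi <- drop(X %*% beta) + u_pop[off$population] + u_fem[off$female_id] + eps
  off$total_length_mm <- len
  off$mass_g <- exp(logsmi) * (len / params$l0_target)^params$b_true
  if (params$prop_missing > 0) {
    for (ff in fems) {
      idx <- which(off$female_id == ff)
      with_seed(substream_seed(seed, paste0("miss:", ff)), {
        hit <- idx[stats::runif(length(idx)) < params$prop_missing]
        kind <- stats::runif(length(hit))
        off$mass_g[hit[kind < 2 / 3]] <- NA
        off$total_length_mm[hit[kind >= 1 / 3]] <- NA
      })
    }
  }
  sim$offspring <- off
  attr(sim$offspring, "truth") <- list(
    logsmi = unname(logsmi), beta = beta, u_pop = u_pop, u_fem = u_fem,
    stage = stage, fem_mode = fem_mode, params = params
  )
  sim
}

# Shared fixed-effect design construction: female-level z-scoring of maternal
# SVL and clutch size (sample SD, n-1), scale-then-square quadratic, and
# treatment contrasts with reference levels larva (offspring stage) and
# mixed (maternal mode). Used by both the generator and the model frame so
# simulation truth and fitted coefficients live in the same basis.
condition_design <- function(offspring, females, stage, fem_mode) {
  fem <- females[match(unique(offspring$female_id), females$female_id), ]
  if (anyNA(fem$female_id)) stopf("offspring reference females missing from female table")
  if (nrow(fem) < 2) stopf("z-scoring undefined with fewer than 2 females")
  zs <- function(x) {
    s <- stats::sd(x)
    if (s == 0) stopf("cannot z-score a constant female covariate")
    (x - mean(x)) / s
  }
  fsvl <- stats::setNames(zs(fem$svl_mm), fem$female_id)[offspring$female_id]
  ncl <- stats::setNames(zs(fem$clutch_size), fem$female_id)[offspring$female_id]
  df <- data.frame(
    fsvl_scaled = fsvl,
    fsvl_scaled_sq = fsvl^2,
    nclutch_scaled = ncl,
    offspring_stage = factor(as.character(stage),
                             levels = c("larva", "mixed", "juvenile")),
    fem_mode = factor(as.character(fem_mode),
                      levels = c("mixed", "larviparous", "pueriparous"))
  )
  df$offspring_stage <- droplevels(df$offspring_stage)
  df$fem_mode <- droplevels(df$fem_mode)
  build_design(df)
}
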