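#' Pipeline configuration
#'
#' Collects everything a full run needs: either paths to delimited input
#' tables (offspring, females, optional population metadata) or transect /
#' condition simulation parameters; analysis toggles; a seed; and an output
#' directory. Every run writes a manifest capturing the configuration and
#' seed, and identical configurations give byte-identical outputs.
#'
#' @param offspring_path,females_path,populations_path CSV inputs (UTF-8,
#'   header row). When `offspring_path` is `NULL` the pipeline simulates its
#'   inputs from `sim_params` / `cond_params`.
#' @param sim_params A [cline_params()] object for simulated runs.
#' @param cond_params A [condition_params()] object for simulated runs.
#' @param exclude_partial_clutches Drop clutches containing unstaged members
#'   from individual-level analyses (ordination and the condition model), the
#'   way ambiguous birth compositions are excluded from individual-level
#'   results. Default `TRUE`.
#' @param ca_variants Contingency-table variants to ordinate.
#' @param seed Integer seed governing all randomness in the run.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(offspring_path = NULL, females_path = NULL,
                            populations_path = NULL,
                            sim_params = cline_params(),
                            cond_params = condition_params(),
                            exclude_partial_clutches = TRUE,
                            ca_variants = c("stacked", "combined"),
                            seed = 1L, out_dir = tempfile("reproclines_run_")) {
  structure(list(
    offspring_path = offspring_path, females_path = females_path,
    populations_path = populations_path,
    sim_params = sim_params, cond_params = cond_params,
    exclude_partial_clutches = exclude_partial_clutches,
    ca_variants = match.arg(ca_variants,
                            c("gill", "pigment", "stacked", "combined"),
                            several.ok = TRUE),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema check (required columns), vocabulary check (stage tokens),
#' referential integrity (every offspring's female exists; every female's
#' population exists in the metadata when given), duplicate detection, and
#' positivity of morphometrics. Violations are returned as a report;
#' [run_pipeline()] refuses to proceed on fatal ones.
#'
#' @param offspring,females Data.frames; `populations` optional.
#' @return Data.frame with columns `severity` (`"fatal"`/`"warning"`),
#'   `check`, `detail`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(offspring, females, populations = NULL) {
  out <- list()
  add <- function(severity, check, detail) {
    out[[length(out) + 1]] <<- data.frame(severity = severity, check = check,
                                          detail = detail)
  }
  need_o <- c("offspring_id", "female_id", "population", "gill_stage",
              "pigment_stage", "mass_g", "total_length_mm")
  miss <- setdiff(need_o, names(offspring))
  if (length(miss)) add("fatal", "offspring schema",
                        paste("missing columns:", paste(miss, collapse = ", ")))
  need_f <- c("female_id", "population", "svl_mm", "clutch_size")
  miss <- setdiff(need_f, names(females))
  if (length(miss)) add("fatal", "female schema",
                        paste("missing columns:", paste(miss, collapse = ", ")))
  if (!length(out)) {
    key <- paste(offspring$female_id, offspring$offspring_id)
    if (anyDuplicated(key)) {
      add("fatal", "duplicate offspring",
          paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    if (anyDuplicated(females$female_id)) {
      add("fatal", "duplicate females",
          paste(unique(females$female_id[duplicated(females$female_id)]),
                collapse = ", "))
    }
    orphan <- setdiff(unique(offspring$female_id), females$female_id)
    if (length(orphan)) add("fatal", "referential integrity",
                            paste("offspring reference unknown female(s):",
                                  paste(orphan, collapse = ", ")))
    tok <- tryCatch({
      parse_stage_pair(offspring$gill_stage, offspring$pigment_stage)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(tok)) add("fatal", "stage vocabulary", tok)
    bad_m <- !is.na(offspring$mass_g) & offspring$mass_g <= 0
    if (any(bad_m)) add("warning", "non-positive mass",
                        paste(offspring$offspring_id[bad_m], collapse = ", "))
    bad_l <- !is.na(offspring$total_length_mm) & offspring$total_length_mm <= 0
    if (any(bad_l)) add("warning", "non-positive total length",
                        paste(offspring$offspring_id[bad_l], collapse = ", "))
    if (!is.null(populations)) {
      orphan_p <- setdiff(unique(females$population), populations$population)
      if (length(orphan_p)) add("fatal", "population metadata",
                                paste("females from population(s) absent from metadata:",
                                      paste(orphan_p, collapse = ", ")))
    }
  }
  if (!length(out)) {
    return(data.frame(severity = character(0), check = character(0),
                      detail = character(0)))
  }
  do.call(rbind, out)
}

read_input <- function(path, what) {
  if (!file.exists(path)) stopf("%s input not found: %s", what, path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full transect analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain inputs (simulate or read),
#' validate, stage newborns, classify clutch and population reproductive
#' modes, write a sampling-table-style population report and proportion
#' tables, test gill-pigmentation independence, run the requested
#' correspondence analyses, compute Scaled Mass Index condition, fit the
#' heteroscedastic mixed model with EMMs, Tukey contrasts, ICC and R2, and
#' write every artifact plus a manifest and a machine-readable results index
#' under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list with every in-memory artifact (tables, test
#'   results, CA objects, model fit and summaries) plus `paths` to the files
#'   written.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)

  if (is.null(cfg$offspring_path)) {
    sim <- simulate_transect(cfg$sim_params)
    sim <- simulate_condition(sim, cfg$cond_params, seed = cfg$seed)
    offspring <- sim$offspring; females <- sim$females
    populations <- sim$populations
  } else {
    offspring <- read_input(cfg$offspring_path, "offspring")
    females <- read_input(cfg$females_path, "female")
    populations <- if (!is.null(cfg$populations_path)) {
      read_input(cfg$populations_path, "population metadata")
    } else NULL
  }

  report <- validate_inputs(offspring, females, populations)
  if (any(report$severity == "fatal")) {
    utils::write.csv(report, pth("validation_FAILED.csv"), row.names = FALSE)
    stopf("validation failed: %s",
          paste(report$detail[report$severity == "fatal"], collapse = "; "))
  }

  clutches <- suppressWarnings(clutch_summaries(offspring))
  pops <- population_summaries(clutches, populations)
  if (!is.null(populations) && "transect_position_km" %in% names(pops) &&
      !anyNA(pops$transect_position_km)) {
    pops <- transect_profile(pops)
  }
  prop_clutch <- suppressMessages(mode_proportions(offspring, "clutch"))
  prop_pop <- suppressMessages(mode_proportions(offspring, "population"))
  rates <- if ("n_females_collected" %in% names(pops) &&
               !anyNA(pops$n_females_collected)) success_rates(pops) else NULL

  # individual-level dataset, optionally excluding ambiguous clutches
  analysis_off <- offspring
  partial <- clutches$female_id[clutches$n_unstaged > 0]
  if (cfg$exclude_partial_clutches && length(partial)) {
    message(sprintf("excluding %d clutch(es) with unstaged members from individual-level analyses: %s",
                    length(partial), paste(partial, collapse = ", ")))
    analysis_off <- offspring[!(offspring$female_id %in% partial), , drop = FALSE]
  }

  chisq <- suppressWarnings(chi_square_independence(analysis_off))
  ca <- lapply(stats::setNames(cfg$ca_variants, cfg$ca_variants), function(v) {
    correspondence_analysis(suppressWarnings(build_contingency(analysis_off, v)))
  })

  off_cond <- add_condition(analysis_off)
  cond_meta <- attr(off_cond, "condition")
  frame <- prepare_frame(off_cond, females)
  fit <- reml_fit(frame)
  emm_mode <- emmeans_tukey(fit, "fem_mode")
  emm_stage <- if (nlevels(frame$offspring_stage) > 1) {
    emmeans_tukey(fit, "offspring_stage")
  } else NULL
  vs <- variance_summary(fit)
  diag <- lmm_diagnostics(fit)

  # --- write artifacts ---
  utils::write.csv(pops, pth("population_report.csv"), row.names = FALSE)
  utils::write.csv(clutches, pth("clutch_summaries.csv"), row.names = FALSE)
  utils::write.csv(prop_clutch, pth("proportions_clutch.csv"), row.names = FALSE)
  utils::write.csv(prop_pop, pth("proportions_population.csv"), row.names = FALSE)
  utils::write.csv(off_cond, pth("offspring_with_smi.csv"), row.names = FALSE)
  for (v in names(ca)) {
    utils::write.csv(biplot_export(ca[[v]]), pth(sprintf("ca_%s_coords.csv", v)),
                     row.names = FALSE)
    write_kv(as.list(c(ca[[v]]$principal_inertias,
                       total_inertia = ca[[v]]$total_inertia)),
             pth(sprintf("ca_%s_inertia.txt", v)))
  }
  utils::write.csv(emm_mode$contrasts, pth("contrasts_fem_mode.csv"),
                   row.names = FALSE)
  if (!is.null(emm_stage)) {
    utils::write.csv(emm_stage$contrasts, pth("contrasts_offspring_stage.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(diag$per_mode_sd, pth("diagnostics_per_mode_sd.csv"),
                   row.names = FALSE)

  index <- c(
    seed = cfg$seed,
    n_offspring = nrow(offspring),
    n_females = nrow(females),
    n_populations = length(unique(offspring$population)),
    pct_excluded_morphometrics = round(attr(cond_meta$exclusions, "pct_excluded"), 4),
    sma_slope = round(cond_meta$sma$b_sma, 6),
    l0_mm = round(cond_meta$l0, 4),
    chisq_statistic = round(chisq$statistic, 6),
    chisq_df = chisq$df,
    chisq_p = format(chisq$p, digits = 6),
    if (!is.null(rates)) c(overall_success_rate_pct = rates$overall),
    sigma_pop = round(fit$sigma_pop, 6),
    sigma_female = round(fit$sigma_female, 6),
    sigma_resid = round(fit$sigma_resid, 6),
    stats::setNames(round(fit$delta, 6), paste0("delta_", names(fit$delta))),
    reml_loglik = round(fit$reml_loglik, 6),
    icc_adjusted = round(vs$icc_adjusted, 6),
    r2_marginal = round(vs$r2_marginal, 6),
    r2_conditional = round(vs$r2_conditional, 6)
  )
  write_kv(as.list(index), pth("results_index.txt"))
  manifest <- c(
    package_version = as.character(utils::packageVersion("reproclines")),
    seed = cfg$seed,
    simulated = is.null(cfg$offspring_path),
    exclude_partial_clutches = cfg$exclude_partial_clutches,
    ca_variants = paste(cfg$ca_variants, collapse = ","),
    if (is.null(cfg$offspring_path)) {
      c(unlist(cfg$sim_params[c("n_populations", "center", "width",
                                "females_per_population", "stage_coupling",
                                "asynchrony_scale", "seed")]),
        sim_positions = paste(round(cfg$sim_params$positions, 3), collapse = ","))
    } else {
      c(offspring_path = cfg$offspring_path, females_path = cfg$females_path)
    }
  )
  write_kv(as.list(manifest), pth("manifest.txt"))

  invisible(list(
    offspring = offspring, females = females, populations = pops,
    clutches = clutches, proportions_clutch = prop_clutch,
    proportions_population = prop_pop, success = rates, chisq = chisq,
    ca = ca, condition = cond_meta, offspring_with_smi = off_cond,
    fit = fit, emm_fem_mode = emm_mode, emm_offspring_stage = emm_stage,
    variance = vs, diagnostics = diag,
    paths = list(out_dir = cfg$out_dir,
                 results_index = pth("results_index.txt"))
  ))
}
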