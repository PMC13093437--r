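#' Reproductive mode vocabulary
#'
#' The same three-level vocabulary describes both clutch (female) and
#' population reproductive modes: `larviparous` (only aquatic larvae born),
#' `pueriparous` (only terrestrial juveniles), `mixed` (anything in between).
#'
#' @return Character vector of the three mode labels.
#' @export
reproductive_modes <- function() c("larviparous", "mixed", "pueriparous")

#' Classify a clutch's reproductive mode from its members' stage pairs
#'
#' A birth is `larviparous` when every member is a pure larva (`L1/L` or
#' `L2/L`) and `pueriparous` when every member is a pure terrestrial juvenile
#' (`P1/P` or `P2/P`). It is `mixed` when either (1) any member shows a mixed
#' phenotype (intermediate or asynchronous gill/pigmentation development), or
#' (2) larvae and juveniles co-occur among siblings.
#'
#' Members with missing stages (unstaged newborns) are dropped with a warning
#' and the clutch is classified from the staged members only; if no member is
#' staged the mode is `NA`.
#'
#' @param gill,pigment Stage codes of the clutch members.
#' @return One of [reproductive_modes()], as character, or `NA`.
#' @export
#' @examples
#' classify_clutch(c("L1", "L1", "L2"), c("L", "L", "L"))  # larviparous
#' classify_clutch(c("L1", "P2"), c("L", "P"))             # mixed
classify_clutch <- function(gill, pigment) {
  if (length(gill) == 0) stopf("cannot classify an empty clutch")
  st <- parse_stage_pair(gill, pigment)
  ph <- classify_offspring(st$gill, st$pigment)
  if (anyNA(ph)) {
    warnf("%d unstaged member(s) dropped; clutch classified from %d staged member(s)",
          sum(is.na(ph)), sum(!is.na(ph)))
    ph <- ph[!is.na(ph)]
  }
  if (length(ph) == 0) return(NA_character_)
  if (all(ph == "larva")) return("larviparous")
  if (all(ph == "juvenile")) return("pueriparous")
  "mixed"
}

#' Classify a population's reproductive mode from its clutch modes
#'
#' A population is `larviparous` or `pueriparous` when all its recorded
#' births share that pure mode; it is `mixed` when any clutch is mixed or
#' when both pure modes co-occur. With no recorded births the mode is
#' undefined (`NA`).
#'
#' @param clutch_modes Character vector of clutch modes (may be empty).
#' @return One of [reproductive_modes()] or `NA_character_`.
#' @export
classify_population <- function(clutch_modes) {
  m <- clutch_modes[!is.na(clutch_modes)]
  if (length(m) == 0) return(NA_character_)
  bad <- setdiff(unique(m), reproductive_modes())
  if (length(bad)) stopf("unknown clutch mode(s): %s", paste(bad, collapse = ", "))
  if (all(m == "larviparous")) return("larviparous")
  if (all(m == "pueriparous")) return("pueriparous")
  "mixed"
}

#' Summarize clutches from an offspring table
#'
#' Aggregates staged offspring per female: phenotype counts, clutch size, and
#' the derived clutch reproductive mode.
#'
#' @param offspring Data.frame with columns `offspring_id`, `female_id`,
#'   `population`, `gill_stage`, `pigment_stage` (tokens or parsed codes).
#' @return Data.frame with one row per female: `female_id`, `population`,
#'   `n_offspring`, `n_larva`, `n_mixed`, `n_juvenile`, `n_unstaged`, `mode`.
#' @export
clutch_summaries <- function(offspring) {
  stopifnot(all(c("female_id", "population", "gill_stage", "pigment_stage")
                %in% names(offspring)))
  if (nrow(offspring) == 0) stopf("empty offspring table")
  st <- parse_stage_pair(offspring$gill_stage, offspring$pigment_stage)
  ph <- classify_offspring(st$gill, st$pigment)
  fem <- unique(offspring[, c("female_id", "population")])
  if (anyDuplicated(fem$female_id)) {
    stopf("female_id appears in more than one population")
  }
  rows <- lapply(seq_len(nrow(fem)), function(i) {
    idx <- offspring$female_id == fem$female_id[i]
    phi <- ph[idx]
    staged <- phi[!is.na(phi)]
    mode <- if (length(staged)) {
      suppressWarnings(classify_clutch(as.character(st$gill[idx]),
                                       as.character(st$pigment[idx])))
    } else NA_character_
    data.frame(
      female_id = fem$female_id[i], population = fem$population[i],
      n_offspring = sum(idx),
      n_larva = sum(staged == "larva"),
      n_mixed = sum(staged == "mixed"),
      n_juvenile = sum(staged == "juvenile"),
      n_unstaged = sum(is.na(phi)),
      mode = mode
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize populations from clutch summaries
#'
#' Derives per-population clutch counts, the population reproductive mode,
#' and the proportions of larviparous / mixed / pueriparous clutches.
#' Optional metadata adds collected-female counts, transect positions, and a
#' field mode designation used only for populations with no recorded births.
#'
#' @param clutches Output of [clutch_summaries()].
#' @param metadata Optional data.frame with columns `population` and any of
#'   `n_females_collected`, `transect_position_km`, `field_mode`; populations
#'   present only in the metadata appear with zero clutches and `NA` mode.
#' @return Data.frame with one row per population.
#' @export
population_summaries <- function(clutches, metadata = NULL) {
  pops <- unique(clutches$population)
  if (!is.null(metadata)) pops <- union(pops, metadata$population)
  rows <- lapply(pops, function(pp) {
    cl <- clutches[clutches$population == pp, , drop = FALSE]
    modes <- cl$mode
    data.frame(
      population = pp,
      n_clutches = nrow(cl),
      n_offspring = sum(cl$n_offspring),
      mode = classify_population(modes),
      p_larviparous = if (nrow(cl)) mean(modes == "larviparous", na.rm = TRUE) else NA_real_,
      p_mixed = if (nrow(cl)) mean(modes == "mixed", na.rm = TRUE) else NA_real_,
      p_pueriparous = if (nrow(cl)) mean(modes == "pueriparous", na.rm = TRUE) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    keep <- intersect(c("population", "n_females_collected",
                        "transect_position_km", "field_mode"),
                      names(metadata))
    out <- merge(out, metadata[, keep, drop = FALSE],
                 by = "population", all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Phenotype and clutch-mode proportion tables
#'
#' At `level = "clutch"` each row is a female with the fractions of her
#' staged offspring that are larvae / mixed / juveniles; at
#' `level = "population"` each row is a population with the fractions of its
#' classified clutches that are larviparous / mixed / pueriparous. Units with
#' nothing to tabulate (no staged offspring, no classified clutches) are
#' omitted with a message. Each returned row sums to one.
#'
#' @param offspring Offspring table (see [clutch_summaries()]).
#' @param level `"clutch"` or `"population"`.
#' @return Data.frame of per-unit proportions.
#' @export
mode_proportions <- function(offspring, level = c("clutch", "population")) {
  level <- match.arg(level)
  cl <- clutch_summaries(offspring)
  if (level == "clutch") {
    staged <- cl$n_larva + cl$n_mixed + cl$n_juvenile
    drop <- staged == 0
    if (any(drop)) {
      message(sprintf("omitting %d clutch(es) with no staged offspring: %s",
                      sum(drop), paste(cl$female_id[drop], collapse = ", ")))
    }
    cl <- cl[!drop, , drop = FALSE]
    tot <- cl$n_larva + cl$n_mixed + cl$n_juvenile
    out <- data.frame(female_id = cl$female_id, population = cl$population,
                      larva = cl$n_larva / tot, mixed = cl$n_mixed / tot,
                      juvenile = cl$n_juvenile / tot)
  } else {
    ps <- population_summaries(cl)
    drop <- is.na(ps$mode)
    if (any(drop)) {
      message(sprintf("omitting %d population(s) with no classified clutches: %s",
                      sum(drop), paste(ps$population[drop], collapse = ", ")))
    }
    ps <- ps[!drop, , drop = FALSE]
    out <- data.frame(population = ps$population,
                      larviparous = ps$p_larviparous, mixed = ps$p_mixed,
                      pueriparous = ps$p_pueriparous)
  }
  rownames(out) <- NULL
  out
}

#' Clutch success rates overall and by reproductive mode
#'
#' Success is the fraction of collected (potentially gravid) females that
#' produced a clutch. Per-mode rates are pooled ratios — total clutches over
#' total females within each mode group — not means of per-population ratios.
#' Populations without a classified mode use their field designation
#' (`field_mode`) when supplied; populations with neither are excluded from
#' per-mode rates but always count toward the overall rate. Percentages are
#' rounded half-up to the nearest integer, as conventionally printed.
#'
#' @param pop_table Data.frame with columns `n_females_collected`,
#'   `n_clutches`, and `mode` (may be `NA`); optional `field_mode` fallback.
#' @return List with `overall` (percent), `by_mode` (data.frame of group,
#'   n_females, n_clutches, rate_pct), `n_females_total`,
#'   `n_clutches_total`, `n_populations_with_births`.
#' @export
success_rates <- function(pop_table) {
  stopifnot(all(c("n_females_collected", "n_clutches", "mode") %in% names(pop_table)))
  nf <- pop_table$n_females_collected
  nc <- pop_table$n_clutches
  if (any(nc > nf, na.rm = TRUE)) stopf("more clutches than collected females")
  if (sum(nf) == 0) stopf("zero collected females: overall rate undefined")
  group <- as.character(pop_table$mode)
  if ("field_mode" %in% names(pop_table)) {
    fm <- tolower(as.character(pop_table$field_mode))
    fm[fm %in% c("na", "")] <- NA
    fm <- sub("^larviparity$", "larviparous", fm)
    fm <- sub("^pueriparity$", "pueriparous", fm)
    group[is.na(group)] <- fm[is.na(group)]
  }
  by_mode <- do.call(rbind, lapply(reproductive_modes(), function(m) {
    idx <- !is.na(group) & group == m
    n_f <- sum(nf[idx]); n_c <- sum(nc[idx])
    data.frame(group = m, n_females = n_f, n_clutches = n_c,
               rate_pct = if (n_f > 0) round_half_up(100 * n_c / n_f) else NA_real_)
  }))
  list(
    overall = round_half_up(100 * sum(nc) / sum(nf)),
    by_mode = by_mode,
    n_females_total = sum(nf),
    n_clutches_total = sum(nc),
    n_populations_with_births = sum(nc > 0)
  )
}

#' Order population summaries along the transect
#'
#' Sorts per-population rows by transect position (ties broken by population
#' identifier) so mode and proportion series can be read as a geographic
#' profile.
#'
#' @param pop_summaries Data.frame with a numeric `transect_position_km`
#'   column (no missing values) and a `population` column.
#' @param decreasing Sort south-to-north (`FALSE`, default) or reverse.
#' @return The same data.frame, reordered.
#' @export
transect_profile <- function(pop_summaries, decreasing = FALSE) {
  pos <- pop_summaries$transect_position_km
  if (is.null(pos) || anyNA(pos)) {
    stopf("every population needs a numeric transect_position_km")
  }
  out <- pop_summaries[order(pos, as.character(pop_summaries$population),
                             decreasing = decreasing), , drop = FALSE]
  rownames(out) <- NULL
  out
}
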