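#' Filter offspring records on morphometric completeness
#'
#' Body-condition analysis needs both mass and total length. Records with
#' either missing or non-positive are excluded; the exclusion report lists
#' every dropped record with its reason and the overall exclusion
#' percentage.
#'
#' @param records Offspring table with `mass_g` and `total_length_mm`.
#' @return List with `kept` (filtered table) and `report` (data.frame of
#'   `offspring_id`, `reason`) carrying attribute `pct_excluded`.
#' @export
filter_morphometrics <- function(records) {
  stopifnot(all(c("mass_g", "total_length_mm") %in% names(records)))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$total_length_mm)] <- "missing total length"
  reason[is.na(records$mass_g)] <- "missing mass"
  reason[is.na(records$mass_g) & is.na(records$total_length_mm)] <- "missing mass and total length"
  reason[!is.na(records$mass_g) & records$mass_g <= 0] <- "non-positive mass"
  reason[!is.na(records$total_length_mm) & records$total_length_mm <= 0] <- "non-positive total length"
  drop <- !is.na(reason)
  if (all(drop)) stopf("all %d records excluded by the morphometric filter", nrow(records))
  report <- data.frame(
    offspring_id = records$offspring_id[drop] %||% which(drop),
    reason = reason[drop]
  )
  attr(report, "pct_excluded") <- 100 * sum(drop) / nrow(records)
  list(kept = records[!drop, , drop = FALSE], report = report)
}

#' Standardized-major-axis allometry of mass on length
#'
#' Fits the allometric relationship between body mass and total length on the
#' natural-log scale. The SMA slope symmetrizes error in both variables:
#' `b_sma = b_ols / r`, where `b_ols` is the ordinary least-squares slope of
#' `ln(mass)` on `ln(length)` and `r` their Pearson correlation; equivalently
#' `|b_sma| = sd(ln mass) / sd(ln length)`. A negative correlation is
#' biologically meaningless for allometry and is rejected rather than
#' silently sign-flipped.
#'
#' @param records Filtered offspring table (see [filter_morphometrics()]).
#' @return List of class `sma_fit`: `b_sma`, `b_ols`, `r`, `n_used`.
#' @export
fit_sma <- function(records) {
  m <- records$mass_g; l <- records$total_length_mm
  if (length(m) < 3) stopf("SMA needs at least 3 records")
  if (any(m <= 0 | l <= 0, na.rm = TRUE) || anyNA(m) || anyNA(l)) {
    stopf("fit_sma expects positive, complete morphometrics; filter first")
  }
  lm_ <- log(m); ll <- log(l)
  if (stats::sd(ll) == 0) stopf("zero variance in ln(length): slope undefined")
  r <- stats::cor(lm_, ll)
  if (abs(r) < 1e-8) stopf("|r| < 1e-8: SMA slope undefined")
  if (r < 0) stopf("negative mass-length correlation: allometry rejected")
  b_ols <- stats::cov(lm_, ll) / stats::var(ll)
  structure(list(b_sma = b_ols / r, b_ols = b_ols, r = r,
                 n_used = length(m)), class = "sma_fit")
}

#' Scaled Mass Index at a reference length
#'
#' Standardizes each individual's mass to the value it would have at the
#' reference total length `l0`: `smi = mass * (l0 / length)^b_sma`. At
#' `length = l0` the index equals the raw mass; on an exact power law with
#' slope `b_sma` the index is constant.
#'
#' @param mass,length Positive morphometrics (g, mm), recycled.
#' @param l0 Reference length, mm (conventionally the mean total length of
#'   the filtered offspring dataset).
#' @param b_sma SMA allometric slope.
#' @return Data.frame with `smi` (g) and `logsmi` (natural log).
#' @export
#' @examples
#' compute_smi(2, 50, 100, 3)  # 16 g
compute_smi <- function(mass, length, l0, b_sma) {
  if (any(mass <= 0, na.rm = TRUE) || any(length <= 0, na.rm = TRUE) || l0 <= 0) {
    stopf("mass, length and l0 must be positive")
  }
  smi <- mass * (l0 / length)^b_sma
  data.frame(smi = smi, logsmi = log(smi))
}

#' Pearson correlation of raw mass and total length
#'
#' Two-sided test of the linear association between untransformed mass and
#' total length, reported before committing to a condition index.
#'
#' @param records Filtered offspring table.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_mass_length <- function(records) {
  if (nrow(records) < 3) stopf("need at least 3 records")
  if (stats::sd(records$mass_g) == 0 || stats::sd(records$total_length_mm) == 0) {
    stopf("degenerate variance: correlation undefined")
  }
  ct <- stats::cor.test(records$mass_g, records$total_length_mm)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}

#' Add Scaled Mass Index columns to an offspring table
#'
#' End-to-end condition step: applies the morphometric filter, computes the
#' reference length `l0` as the arithmetic mean total length of the filtered
#' dataset, fits the pooled SMA allometry, and appends `smi` and `logsmi`
#' columns (NA for excluded records).
#'
#' @param offspring Offspring table.
#' @return The table with `smi`/`logsmi` columns; the `sma_fit`, `l0`, and
#'   exclusion report are attached as attribute `"condition"`.
#' @export
add_condition <- function(offspring) {
  flt <- filter_morphometrics(offspring)
  sma <- fit_sma(flt$kept)
  l0 <- mean(flt$kept$total_length_mm)
  offspring$smi <- NA_real_
  offspring$logsmi <- NA_real_
  keep <- offspring$offspring_id %in% flt$kept$offspring_id
  res <- compute_smi(offspring$mass_g[keep], offspring$total_length_mm[keep],
                     l0, sma$b_sma)
  offspring$smi[keep] <- res$smi
  offspring$logsmi[keep] <- res$logsmi
  attr(offspring, "condition") <- list(sma = sma, l0 = l0,
                                       exclusions = flt$report)
  offspring
}
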