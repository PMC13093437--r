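#' Build population-by-stage contingency tables
#'
#' Cross-tabulates staged offspring by population against stage categories.
#' Variants: `"gill"` (4 columns), `"pigment"` (3 columns), `"stacked"`
#' (the two blocks side by side, 7 columns — each individual contributes one
#' count to each block; this is how the two characters' levels are ordinated
#' jointly against populations), and `"combined"` (one column per observed
#' gill-pigmentation pair, labelled like `"L1_L"`; never-observed pairs do
#' not enter). Populations with no staged offspring are dropped with a
#' warning, as are all-zero columns.
#'
#' @param offspring Offspring table with `population`, `gill_stage`,
#'   `pigment_stage`.
#' @param variant One of `"gill"`, `"pigment"`, `"stacked"`, `"combined"`.
#' @return Integer matrix with population rownames and stage colnames.
#' @export
build_contingency <- function(offspring,
                              variant = c("gill", "pigment", "stacked", "combined")) {
  variant <- match.arg(variant)
  if (nrow(offspring) == 0) stopf("empty offspring table")
  st <- parse_stage_pair(offspring$gill_stage, offspring$pigment_stage)
  staged <- !is.na(st$gill) & !is.na(st$pigment)
  pop <- factor(offspring$population[staged],
                levels = unique(offspring$population))
  g <- st$gill[staged]; pg <- st$pigment[staged]
  tab <- switch(variant,
    gill = table(pop, gill = g),
    pigment = table(pop, pigment = pg),
    stacked = cbind(unclass(table(pop, g)), unclass(table(pop, pg))),
    combined = table(pop, pair = factor(paste(g, pg, sep = "_")))
  )
  tab <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  zero_rows <- rowSums(tab) == 0
  if (any(zero_rows)) {
    warnf("dropping population(s) with no staged offspring: %s",
          paste(rownames(tab)[zero_rows], collapse = ", "))
    tab <- tab[!zero_rows, , drop = FALSE]
  }
  zero_cols <- colSums(tab) == 0
  if (any(zero_cols)) {
    warnf("dropping all-zero stage column(s): %s",
          paste(colnames(tab)[zero_cols], collapse = ", "))
    tab <- tab[, !zero_cols, drop = FALSE]
  }
  tab
}

#' Pearson chi-square test of gill-pigmentation independence
#'
#' Cross-tabulates individuals by gill and pigmentation stage and applies
#' Pearson's test without continuity correction. Zero-margin rows/columns are
#' dropped with a warning before testing. The small-cell approximation
#' warning from the underlying test is muffled; with sparse tables the
#' p-value is approximate and should be read qualitatively.
#'
#' @param offspring Offspring table, or a pre-built cross-tab matrix of gill
#'   (rows) by pigmentation (columns) counts.
#' @return List with `statistic`, `df`, `p`, `table`.
#' @export
chi_square_independence <- function(offspring) {
  if (is.matrix(offspring) || is.table(offspring)) {
    tab <- as.matrix(offspring)
  } else {
    st <- parse_stage_pair(offspring$gill_stage, offspring$pigment_stage)
    staged <- !is.na(st$gill) & !is.na(st$pigment)
    tab <- unclass(table(st$gill[staged], st$pigment[staged]))
  }
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warnf("dropping zero-margin row(s)/column(s) before testing")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least a 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, table = tab)
}

#' Correspondence analysis of a contingency table
#'
#' Classical CA via singular value decomposition of the matrix of
#' standardized residuals `S = Dr^{-1/2} (P - r c') Dc^{-1/2}`, where `P` is
#' the correspondence matrix and `r`, `c` the row and column masses.
#' Principal inertias are the squared singular values and sum to the table's
#' total inertia, which equals the Pearson chi-square statistic divided by
#' the grand total. Principal coordinates are mass-rescaled singular vectors
#' scaled by the singular values; standard column coordinates (for the
#' asymmetric biplot) omit that scaling. Axis signs are fixed
#' deterministically so that the largest-magnitude standard column loading on
#' each axis is positive. An exactly independent table has no non-trivial
#' dimension and is returned with zero inertia, not an error.
#'
#' @param tab Non-negative count matrix (rows: populations; columns: stage
#'   categories), at least 2 x 2 after pruning.
#' @return List of class `ca_result`: `principal_inertias`, `pct_variance`,
#'   `row_coords_principal`, `col_coords_principal`, `col_coords_standard`,
#'   `row_masses`, `col_masses`, `total_inertia`, `n`.
#' @export
correspondence_analysis <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("row", seq_len(nrow(tab)))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("col", seq_len(ncol(tab)))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need >= 2 rows and >= 2 columns")
  n <- sum(tab)
  P <- tab / n
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  kmax <- min(nrow(tab), ncol(tab)) - 1L
  keep <- which(sv$d > max(sv$d[1], 1) * 1e-10)
  keep <- keep[keep <= kmax]
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: largest |standard column loading| positive on each axis
  Vstd <- diag(1 / sqrt(cc)) %*% V
  for (k in seq_along(d)) {
    j <- which.max(abs(Vstd[, k]))
    if (Vstd[j, k] < 0) {
      V[, k] <- -V[, k]; U[, k] <- -U[, k]; Vstd[, k] <- -Vstd[, k]
    }
  }
  lam <- d^2
  dims <- if (length(d)) paste0("Dim", seq_along(d)) else character(0)
  if (length(d)) {
    row_p <- diag(1 / sqrt(r)) %*% U %*% diag(d, length(d))
    col_p <- diag(1 / sqrt(cc)) %*% V %*% diag(d, length(d))
  } else {
    row_p <- matrix(0, nrow(tab), 0)
    col_p <- Vstd <- matrix(0, ncol(tab), 0)
  }
  dn <- if (length(dims)) dims else NULL
  dimnames(row_p) <- list(rownames(tab), dn)
  dimnames(col_p) <- list(colnames(tab), dn)
  dimnames(Vstd) <- list(colnames(tab), dn)
  structure(list(
    principal_inertias = stats::setNames(lam, dims),
    pct_variance = if (length(lam)) stats::setNames(100 * lam / sum(lam), dims)
                   else numeric(0),
    row_coords_principal = row_p,
    col_coords_principal = col_p,
    col_coords_standard = Vstd,
    row_masses = r, col_masses = cc,
    total_inertia = sum(lam), n = n
  ), class = "ca_result")
}

#' Export biplot coordinates from a correspondence analysis
#'
#' Symmetric biplots use principal coordinates for both rows and columns;
#' asymmetric biplots pair principal row coordinates with standard column
#' coordinates so column points show their contribution directions. The
#' first `ndim` dimensions are exported with their explained-variance
#' percentages.
#'
#' @param ca A `ca_result`.
#' @param style `"symmetric"` or `"asymmetric"`.
#' @param ndim Number of dimensions to export (default up to 2).
#' @return Data.frame with `label`, `set` (`"row"`/`"column"`), coordinate
#'   columns, and attribute `pct_variance`.
#' @export
biplot_export <- function(ca, style = c("symmetric", "asymmetric"),
                          ndim = min(2L, length(ca$principal_inertias))) {
  style <- match.arg(style)
  k <- length(ca$principal_inertias)
  if (k < 1) stopf("no non-trivial CA dimension to export")
  if (ndim < 1 || ndim > k) stopf("requested %d dimensions but only %d exist", ndim, k)
  cols <- if (style == "symmetric") ca$col_coords_principal else ca$col_coords_standard
  out <- rbind(
    data.frame(label = rownames(ca$row_coords_principal), set = "row",
               ca$row_coords_principal[, seq_len(ndim), drop = FALSE],
               check.names = FALSE),
    data.frame(label = rownames(cols), set = "column",
               cols[, seq_len(ndim), drop = FALSE], check.names = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "pct_variance") <- ca$pct_variance[seq_len(ndim)]
  out
}
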