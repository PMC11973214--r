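.GROUP_LEVELS <- c("CN", "CDR0", "CDR0.5", "CDR1", "CDR2")

.checkCohortTable <- function(table, score) {
  stopifnot(is.data.frame(table))
  need <- c("age", "group", score)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("cohort table lacks columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(as.character(table$group)), .GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("unknown group labels: %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(.GROUP_LEVELS, collapse = ", ")), call. = FALSE)
  if (any(table$age <= 0)) stop("ages must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Linear fit of a regional score against chronological age
#'
#' Ordinary least squares of the score on age, with the coefficient of
#' determination and the slope p-value. Under the assumption that
#' morphological age tracks chronological age, the aging score should grow
#' linearly with age (slope near 1 relative to the reference template age).
#'
#' @param records Data.frame with an \code{age} column and the score column.
#' @param score Which score column to fit (\code{"AS"} or \code{"ADS"}, or
#'   any numeric column name).
#' @return A list: \code{slope}, \code{intercept}, \code{r2}, \code{p}
#'   (slope p-value) and \code{fit} (the \code{lm} object, from which 95\%
#'   confidence bands can be predicted for plotting).
#' @export
fitScoreVsAge <- function(records, score = c("AS", "ADS")) {
  score <- if (length(score) > 1L) match.arg(score) else score
  stopifnot(score %in% names(records), "age" %in% names(records))
  if (nrow(records) < 3L)
    stop("need at least 3 records for the age fit", call. = FALSE)
  if (stats::var(records$age) == 0)
    stop("ages have zero variance; the fit is degenerate", call. = FALSE)
  fit <- stats::lm(stats::reformulate("age", response = score),
                   data = records)
  if (stats::var(records[[score]]) == 0)   # constant score: no age trend
    return(list(slope = 0, intercept = mean(records[[score]]), r2 = 0,
                p = 1, fit = fit))
  sm <- suppressWarnings(summary(fit))   # perfect fits warn; fine for synthetic data
  co <- sm$coefficients
  list(slope = unname(co["age", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r2 = sm$r.squared,
       p = unname(co["age", "Pr(>|t|)"]),
       fit = fit)
}

#' ANCOVA age adjustment with CN-mean centering
#'
#' Removes the chronological-age effect from a score before group
#' comparison: a common-slope additive model \code{score ~ age + group} is
#' fitted across all groups, the age effect
#' \eqn{\beta_{age} (age - \bar{age}_{CN})} is subtracted from each raw
#' score, and the cognitively normal group's mean of the adjusted scores is
#' subtracted so that CN centers at zero. The covariate centering point
#' (mean CN age) only shifts all groups equally and cancels in between-group
#' contrasts.
#'
#' @param table Cohort data.frame with \code{age}, \code{group} and the score
#'   column; the CN group must be present and every group needs at least two
#'   rows.
#' @param score Score column name (\code{"AS"} or \code{"ADS"}).
#' @return The table with an added column \code{<score>.adj}.
#' @export
ancovaAdjust <- function(table, score = c("AS", "ADS")) {
  score <- if (length(score) > 1L) match.arg(score) else score
  .checkCohortTable(table, score)
  if (!any(table$group == "CN"))
    stop("ANCOVA adjustment requires a CN group", call. = FALSE)
  counts <- table(factor(table$group, levels = unique(table$group)))
  if (any(counts < 2L))
    stop(sprintf("every group needs >= 2 rows; too small: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  df <- table
  df$group <- factor(as.character(df$group),
                     levels = intersect(.GROUP_LEVELS, unique(df$group)))
  fit <- stats::lm(stats::reformulate(c("age", "group"), response = score),
                   data = df)
  betaAge <- stats::coef(fit)["age"]
  cnAge <- mean(df$age[df$group == "CN"])
  adj <- df[[score]] - betaAge * (df$age - cnAge)
  adj <- adj - mean(adj[df$group == "CN"])
  table[[paste0(score, ".adj")]] <- as.numeric(adj)
  table
}

#' Cohen's d standardized mean difference
#'
#' Pooled-standard-deviation Cohen's d with \eqn{n - 1} denominators; the
#' sign is \code{mean(x) - mean(y)} (negative when the first group is lower).
#'
#' @param x,y Numeric vectors of scores for the two groups.
#' @return Cohen's d.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
             (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Effect-size band for a Cohen's d value
#'
#' Bands on \eqn{|d|}: below 0.35 none, \[0.35, 0.65) medium, \[0.65, 0.9)
#' large, 0.9 and above very large.
#'
#' @param d Numeric vector of Cohen's d values.
#' @return Character vector of band labels.
#' @examples
#' effectSizeBand(c(-0.40, -0.70, -0.95))
#' @export
effectSizeBand <- function(d) {
  a <- abs(d)
  ifelse(a < 0.35, "none",
  ifelse(a < 0.65, "medium",
  ifelse(a < 0.9, "large", "very large")))
}

#' Significance band for a (corrected) p-value
#'
#' The annotation legend used in the group-comparison figures:
#' ns for p > 0.05; * for 0.01 < p <= 0.05; ** for 0.001 < p <= 0.01;
#' *** for 0.0001 < p <= 0.001; **** for p <= 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of band labels.
#' @export
significanceBand <- function(p) {
  ifelse(p > 0.05, "ns",
  ifelse(p > 0.01, "*",
  ifelse(p > 0.001, "**",
  ifelse(p > 0.0001, "***", "****"))))
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Independent two-sample t-tests (Welch by default; \code{equalVar = TRUE}
#' for the classic pooled test) on each group pair, Bonferroni-corrected over
#' the number of tested pairs, with pooled-SD Cohen's d and the significance
#' and effect-size bands. Groups with fewer than \code{minGroupSize} rows are
#' excluded from testing (with a notice), mirroring the exclusion of
#' undersized clinical stages from statistical testing.
#'
#' @param table Cohort data.frame with \code{group} and the score column.
#' @param score Score column to compare (use the \code{.adj} column for
#'   age-adjusted comparisons).
#' @param pairs Optional list of length-2 character vectors; default all
#'   pairs of testable groups in clinical-stage order.
#' @param equalVar Use the pooled-variance t-test instead of Welch.
#' @param minGroupSize Minimum rows for a group to be tested (default 5).
#' @return A data.frame with one row per pair: \code{group1}, \code{group2},
#'   \code{n1}, \code{n2}, \code{t}, \code{df}, \code{p}, \code{pBonf},
#'   \code{cohenD}, \code{significance}, \code{effectBand}.
#' @export
pairwiseTests <- function(table, score, pairs = NULL, equalVar = FALSE,
                          minGroupSize = 5L) {
  stopifnot(score %in% names(table), "group" %in% names(table))
  grp <- as.character(table$group)
  counts <- table(grp)
  testable <- names(counts)[counts >= minGroupSize]
  dropped <- setdiff(names(counts), testable)
  if (length(dropped))
    message(sprintf("excluded from testing (n < %d): %s", minGroupSize,
                    paste(dropped, collapse = ", ")))
  testable <- intersect(.GROUP_LEVELS, testable)
  if (is.null(pairs)) {
    if (length(testable) < 2L)
      stop("fewer than two testable groups", call. = FALSE)
    pairs <- utils::combn(testable, 2L, simplify = FALSE)
  } else {
    pairs <- Filter(function(p) all(p %in% testable), pairs)
    if (!length(pairs)) stop("no requested pair is testable", call. = FALSE)
  }
  nComp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- table[[score]][grp == pr[1]]
    y <- table[[score]][grp == pr[2]]
    tt <- stats::t.test(x, y, var.equal = equalVar)
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x), n2 = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, pBonf = min(1, tt$p.value * nComp),
               cohenD = cohensD(x, y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significance <- significanceBand(out$pBonf)
  out$effectBand <- effectSizeBand(out$cohenD)
  out
}
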