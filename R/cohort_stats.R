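STUDY_WEEKS <- c(0, 2, 4, 6, 8, 12, 18, 24)

#' Assemble the cohort analysis table
#'
#' Joins per-eye summary rows (one per animal/eye/week; see
#' [summarise_eye()] and [write_eye_summary()]) with intraocular-pressure
#' measurements. Rows are keyed by `(animal, eye, week)` and must be
#' unique; weeks outside the study grid {0, 2, 4, 6, 8, 12, 18, 24}
#' trigger a warning.
#'
#' @param summaries data frame of per-eye summaries with at least
#'   `animal`, `eye`, `week` columns.
#' @param iop optional data frame with `animal`, `eye`, `week`,
#'   `iop_mmHg`.
#' @return a tibble of class `cohort_table`.
#' @export
build_cohort_table <- function(summaries, iop = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("animal", "eye", "week") %in% names(summaries)))
  tab <- tibble::as_tibble(summaries)
  if (!is.null(iop)) {
    stopifnot(all(c("animal", "eye", "week", "iop_mmHg") %in% names(iop)))
    tab <- tibble::as_tibble(
      merge(tab[, setdiff(names(tab), "iop_mmHg")], iop,
            by = c("animal", "eye", "week"), all.x = TRUE, sort = TRUE))
  }
  key <- paste(tab$animal, tab$eye, tab$week)
  if (anyDuplicated(key))
    stop("duplicate (animal, eye, week) rows in the cohort table",
         call. = FALSE)
  if (!all(tab$week %in% STUDY_WEEKS))
    warning("weeks outside the study grid {",
            paste(STUDY_WEEKS, collapse = ","), "}")
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with
#' the sample mean and standard deviation -- the screening step before
#' parametric group comparisons.
#'
#' @param values numeric vector, at least 5 observations with non-zero
#'   variance.
#' @return list with `statistic`, `p_value`, `n`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5)
    stop("insufficient data: need at least 5 observations", call. = FALSE)
  if (sd(values) == 0)
    stop("insufficient variance: values are constant", call. = FALSE)
  kt <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values))
}

#' One-way ANOVA across cohorts with Bonferroni-adjusted pairwise tests
#'
#' Compares a response across groups at one study week: one-way ANOVA for
#' the omnibus F, then all pairwise Welch t-tests with Bonferroni
#' adjustment (`p_adj = min(1, m * p)` over the `m` comparisons). Each
#' (animal, eye, week) row counts as one observation. Groups with fewer
#' than 2 observations are dropped with a warning.
#'
#' @param table a [build_cohort_table()] result (or any data frame).
#' @param response name of the response column.
#' @param group name of the grouping column (default `"cohort"`).
#' @param week optional study week to subset to.
#' @param alpha significance level for the `significant` flag.
#' @return an object of class `anova_result`: `F_value`, `p_value`,
#'   `df`, `groups`, `n_per_group`, and a `pairwise` tibble with raw and
#'   Bonferroni-adjusted p-values.
#' @export
groupwise_anova <- function(table, response, group = "cohort",
                            week = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(table), response %in% names(table),
            group %in% names(table))
  if (!is.null(week)) table <- table[table$week %in% week, , drop = FALSE]
  y <- table[[response]]
  g <- as.character(table[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]

  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    y <- y[keep]; g <- g[keep]
  }
  lev <- if (all(unique(g) %in% c("MsDx", "MsDxF", "control"))) {
    intersect(c("MsDx", "MsDxF", "control"), unique(g))
  } else sort(unique(g))
  if (length(lev) < 2)
    stop("need at least 2 groups with >= 2 observations each",
         call. = FALSE)
  gf <- factor(g, levels = lev)

  fit <- aov(y ~ gf)
  an <- anova(fit)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(k) {
    a <- y[gf == pairs[1, k]]; b <- y[gf == pairs[2, k]]
    tt <- t.test(a, b)    # Welch
    tibble::tibble(group1 = pairs[1, k], group2 = pairs[2, k],
                   t = unname(tt$statistic), p_raw = tt$p.value,
                   p_adj = min(1, m * tt$p.value))
  })
  pw <- do.call(rbind, pw)
  pw$significant <- pw$p_adj < alpha
  structure(
    list(F_value = an$`F value`[1], p_value = an$`Pr(>F)`[1],
         df = unname(an$Df), groups = lev,
         n_per_group = as.integer(table(gf)), pairwise = pw,
         alpha = alpha, response = response, week = week),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s%s: F(%d,%d) = %.3f, p = %.4g\n",
              x$response,
              if (is.null(x$week)) "" else paste0(" @ week ", x$week),
              x$df[1], x$df[2], x$F_value, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' Lagged Pearson correlation between two eye-level measures
#'
#' Pearson correlation between one measure at one week and another
#' measure at another week, paired within (animal, eye) -- e.g. IOP at
#' week 2 against VIT/RPE intensity at week 24 -- optionally restricted
#' to a cohort, sex or eye side. Strength labels follow the convention
#' |r| < 0.4 weak, 0.4-0.7 moderate, > 0.7 strong, signed as direct or
#' inverse.
#'
#' @param table a [build_cohort_table()] result.
#' @param measure_x,measure_y column names of the two measures.
#' @param week_x,week_y study weeks of the two measures.
#' @param cohort,sex,eye optional subgroup filters.
#' @return an object of class `correlation_result`: `r`, `p_value`, `n`,
#'   `strength` (`"weak"`/`"moderate"`/`"strong"`), `direction`
#'   (`"direct"`/`"inverse"`), and the pair description.
#' @export
lagged_correlations <- function(table, measure_x, week_x,
                                measure_y, week_y,
                                cohort = NULL, sex = NULL, eye = NULL) {
  stopifnot(is.data.frame(table),
            all(c(measure_x, measure_y, "animal", "week") %in% names(table)))
  for (f in c("cohort", "sex", "eye")) {
    val <- get(f)
    if (!is.null(val) && f %in% names(table))
      table <- table[table[[f]] %in% val, , drop = FALSE]
  }
  eye_col <- if ("eye" %in% names(table)) table$eye else "?"
  key <- paste(table$animal, eye_col)
  xs <- table[table$week == week_x, , drop = FALSE]
  ys <- table[table$week == week_y, , drop = FALSE]
  kx <- paste(xs$animal, if ("eye" %in% names(xs)) xs$eye else "?")
  ky <- paste(ys$animal, if ("eye" %in% names(ys)) ys$eye else "?")
  common <- intersect(kx, ky)
  x <- xs[[measure_x]][match(common, kx)]
  y <- ys[[measure_y]][match(common, ky)]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("insufficient data: need >= 3 paired observations", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  strength <- if (abs(r) < 0.4) "weak"
              else if (abs(r) <= 0.7) "moderate" else "strong"
  structure(
    list(pair = sprintf("%s@%sw vs %s@%sw", measure_x, week_x,
                        measure_y, week_y),
         r = r, p_value = ct$p.value, n = length(x),
         strength = strength,
         direction = if (r < 0) "inverse" else "direct"),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: r = %.3f (%s %s), p = %.4g, n = %d\n",
              x$pair, x$r, x$direction, x$strength, x$p_value, x$n))
  invisible(x)
}
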