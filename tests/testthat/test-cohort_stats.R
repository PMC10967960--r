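test_that("KS normality screen behaves on normal and non-normal samples", {
  p_norm <- vapply(1:10, function(s) {
    set.seed(s); normality_test(rnorm(1000))$p_value
  }, numeric(1))
  expect_gte(sum(p_norm > 0.05), 9)
  set.seed(1)
  expect_lt(normality_test(runif(1000))$p_value, 0.05)
  expect_error(normality_test(rnorm(4)), "insufficient data")
  expect_error(normality_test(rep(1, 10)), "insufficient variance")
})

test_that("identical group values give F = 0 and p = 1", {
  tab <- tibble::tibble(
    animal = paste0("a", 1:9), eye = "RE", week = 4,
    cohort = rep(c("MsDx", "MsDxF", "control"), each = 3),
    y = rep(c(1, 2, 3), times = 3))
  res <- groupwise_anova(tab, "y", week = 4)
  expect_equal(res$F_value, 0)
  expect_equal(res$p_value, 1)
})

test_that("Bonferroni adjustment is exact m-fold scaling, capped at 1", {
  tab <- sim_table(c(0, 0.3, 2), n = 12, seed = 2)
  res <- groupwise_anova(tab, "y", week = 4)
  expect_equal(res$pairwise$p_adj,
               pmin(1, nrow(res$pairwise) * res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(3)
  tab <- tibble::tibble(animal = paste0("a", 1:24), eye = "RE", week = 0,
                        cohort = rep(c("MsDx", "control"), each = 12),
                        y = rnorm(24, rep(c(0, 1), each = 12)))
  res <- suppressWarnings(groupwise_anova(tab, "y"))
  tt <- t.test(y ~ cohort, data = tab, var.equal = TRUE)
  expect_equal(res$F_value, unname(tt$statistic)^2)
})

test_that("pairwise significance pattern tracks the true group means", {
  hits <- vapply(1:10, function(s) {
    tab <- sim_table(c(0, 0, 2), n = 30, seed = s)
    pw <- groupwise_anova(tab, "y", week = 4)$pairwise
    sig <- pw$significant[order(paste(pw$group1, pw$group2))]
    # pairs in order: MsDx-MsDxF (ns), MsDx-control (sig), MsDxF-control (sig)
    identical(unname(sig), c(FALSE, TRUE, TRUE))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("groups below two observations are dropped with a warning", {
  tab <- sim_table(c(0, 1, 2), n = 5, seed = 4)
  tab <- tab[tab$cohort != "control" | seq_len(nrow(tab)) %% 5 == 0, ]
  tab_small <- tab[tab$cohort != "MsDxF" | seq_len(nrow(tab)) %% 5 == 0, ]
  expect_warning(res <- groupwise_anova(tab, "y", week = 4), "dropping")
  expect_equal(length(res$groups), 2)
  expect_error(suppressWarnings(
    groupwise_anova(tab_small[tab_small$cohort != "MsDx", ], "y", week = 4)),
    "at least 2 groups")
})

test_that("perfect linear association gives r = 1", {
  tab <- make_corr_table(1:10, 2 * (1:10))
  res <- lagged_correlations(tab, "iop_mmHg", 2, "vit_rpe", 24)
  expect_equal(res$r, 1)
  expect_equal(res$n, 10)
  expect_equal(res$strength, "strong")
  expect_equal(res$direction, "direct")
})

test_that("independent variables give small r in most seeds", {
  small <- vapply(1:10, function(s) {
    set.seed(s)
    tab <- make_corr_table(rnorm(100), rnorm(100))
    abs(lagged_correlations(tab, "iop_mmHg", 2, "vit_rpe", 24)$r) < 0.2
  }, logical(1))
  expect_gte(sum(small), 9)
})

test_that("strong correlation at small n is recovered on average", {
  rs <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(8)
    y <- 0.85 * x + sqrt(1 - 0.85^2) * rnorm(8)
    lagged_correlations(make_corr_table(x, y), "iop_mmHg", 2,
                        "vit_rpe", 24)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.85), 0.1)
})

test_that("correlation is symmetric and affine-invariant", {
  set.seed(7)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  r_xy <- lagged_correlations(make_corr_table(x, y), "iop_mmHg", 2,
                              "vit_rpe", 24)$r
  r_yx <- lagged_correlations(make_corr_table(y, x), "iop_mmHg", 2,
                              "vit_rpe", 24)$r
  expect_equal(r_xy, r_yx)
  r_aff <- lagged_correlations(make_corr_table(3 * x + 5, 0.5 * y - 2),
                               "iop_mmHg", 2, "vit_rpe", 24)$r
  expect_equal(r_aff, r_xy)
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(
    lagged_correlations(make_corr_table(1:2, 1:2), "iop_mmHg", 2,
                        "vit_rpe", 24), "insufficient data")
  expect_error(
    lagged_correlations(make_corr_table(rep(1, 5), 1:5), "iop_mmHg", 2,
                        "vit_rpe", 24), "zero variance")
})

test_that("strength labels follow the 0.4 / 0.7 convention with sign", {
  set.seed(11)
  x <- rnorm(200)
  mk <- function(rho) {
    y <- rho * x + sqrt(1 - rho^2) * rnorm(200)
    lagged_correlations(make_corr_table(x, y), "iop_mmHg", 2, "vit_rpe", 24)
  }
  expect_equal(mk(0.1)$strength, "weak")
  expect_equal(mk(0.55)$strength, "moderate")
  expect_equal(mk(0.95)$strength, "strong")
  expect_equal(mk(-0.95)$direction, "inverse")
})

test_that("cohort table enforces unique keys and joins IOP", {
  summaries <- tibble::tibble(animal = c("a1", "a1", "a2"),
                              eye = c("RE", "LE", "RE"),
                              week = c(2, 2, 2), vit_rpe = c(0.1, 0.2, 0.3))
  iop <- tibble::tibble(animal = c("a1", "a2"), eye = "RE", week = 2,
                        iop_mmHg = c(15, 22))
  tab <- build_cohort_table(summaries, iop)
  expect_equal(tab$iop_mmHg[tab$animal == "a2" & tab$eye == "RE"], 22)
  expect_error(build_cohort_table(rbind(summaries, summaries[1, ])),
               "duplicate")
  expect_warning(build_cohort_table(
    tibble::tibble(animal = "a1", eye = "RE", week = 3, vit_rpe = 0.1)),
    "study grid")
})
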