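frame_from_counts <- function(a, b, c, d) {
  data.table::data.table(
    outcome_fatal = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    exposure = factor(c(rep("yes", a + b), rep("no", c + d)),
                      levels = c("no", "yes")))
}

test_that("logistic single-factor OR equals the closed-form 2x2 odds ratio", {
  fr <- frame_from_counts(10, 20, 30, 240)
  fit <- univariate_logit(fr, "outcome_fatal", "exposure")
  expect_equal(fit$or_table$or[fit$or_table$level == "yes"],
               (10 * 240) / (20 * 30), tolerance = 1e-8)
  expect_equal(fit$or_table$or[fit$or_table$level == "no"], 1)
  # balanced data: coefficient zero
  fr2 <- frame_from_counts(5, 5, 5, 5)
  fit2 <- univariate_logit(fr2, "outcome_fatal", "exposure")
  expect_equal(log(fit2$or_table$or[2]), 0, tolerance = 1e-6)
})

test_that("oracle equivalence holds across random 2x2 configurations", {
  set.seed(33)
  for (i in 1:25) {
    cells <- sample(3:200, 4, replace = TRUE)
    fr <- frame_from_counts(cells[1], cells[2], cells[3], cells[4])
    fit <- univariate_logit(fr, "outcome_fatal", "exposure")
    expect_equal(fit$or_table$or[2],
                 (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-8)
  }
})

test_that("quasi-separation is reported as an error naming the culprit", {
  fr <- frame_from_counts(40, 0, 10, 200)
  expect_error(univariate_logit(fr, "outcome_fatal", "exposure"),
               "separation")
})

test_that("planted class effect is recovered by the univariate fit", {
  set.seed(37)
  n <- 20000
  cls <- factor(sample(c("C3", "C5"), n, replace = TRUE, prob = c(0.3, 0.7)),
                levels = c("C3", "C5"))
  lp <- -3 + log(3.55) * (cls == "C5")
  y <- rbinom(n, 1, plogis(lp))
  fr <- data.table::data.table(outcome_fatal = y, drug_class = cls)
  fit <- univariate_logit(fr, "outcome_fatal", "drug_class", reference = "C3")
  or <- fit$or_table$or[fit$or_table$level == "C5"]
  expect_gt(or, 3.0)
  expect_lt(or, 4.2)
})

test_that("RCS basis has k-1 columns, linear tails and self-consistency", {
  set.seed(39)
  x <- c(runif(500, 0, 100))
  b3 <- rcs_basis(x, 3)
  expect_equal(ncol(b3), 2)
  b5 <- rcs_basis(x, 5)
  expect_equal(ncol(b5), 4)
  knots <- attr(b5, "knots")
  expect_equal(knots, unname(quantile(x, c(.05, .275, .5, .725, .95),
                                      type = 7)))
  # tail linearity: second differences vanish outside the boundary knots
  coefs <- c(0.03, -0.5, 1.2, -0.9)  # arbitrary spline in the basis span
  grid_lo <- seq(min(x) - 30, knots[1] - 0.1, length.out = 50)
  grid_hi <- seq(knots[5] + 0.1, max(x) + 30, length.out = 50)
  for (g in list(grid_lo, grid_hi)) {
    f <- rcs_basis(g, knots = knots) %*% coefs
    expect_lt(max(abs(diff(diff(f)))), 1e-8 * max(1, max(abs(f))))
  }
  # regression on the basis recovers a function built from the same basis
  y <- drop(b5 %*% coefs) + 2.5
  fit <- lm(y ~ b5)
  expect_lt(max(abs(resid(fit))), 1e-8)
})

test_that("fewer distinct values than knots is an error", {
  expect_error(rcs_basis(rep(c(1, 2), 50), 3), "distinct")
})

test_that("AIC knot selection is reproducible and minimal, with honest type-I error", {
  set.seed(43)
  n <- 6000
  age <- runif(n, 5, 90)
  y <- rbinom(n, 1, plogis(-2 + 0.015 * age))
  fr <- data.table::data.table(outcome_fatal = y, age_years = age)
  f1 <- fit_rcs_logit(fr, "outcome_fatal", "age_years")
  f2 <- fit_rcs_logit(fr, "outcome_fatal", "age_years")
  expect_equal(f1$k, f2$k)
  aics <- f1$aic_table$aic
  expect_equal(min(aics, na.rm = TRUE), aics[f1$aic_table$k == f1$k])
})

test_that("a planted U-shape is detected with the vertex localized", {
  set.seed(47)
  n <- 20000
  age <- pmin(pmax(rnorm(n, 45, 20), 1), 95)
  lp <- -3 + 0.03 * abs(age - 30)
  y <- rbinom(n, 1, plogis(lp))
  fr <- data.table::data.table(outcome_fatal = y, age_years = age)
  fit <- fit_rcs_logit(fr, "outcome_fatal", "age_years")
  expect_lt(fit$p_nonlinear, 0.001)
  curve <- adjusted_curve(fit)
  expect_gt(curve$minimizer, 25)
  expect_lt(curve$minimizer, 35)
  # probabilities stay in (0,1)
  expect_true(all(curve$curve$probability > 0 & curve$curve$probability < 1))
})

test_that("interaction test distinguishes planted modification from none", {
  set.seed(51)
  n <- 20000
  age <- runif(n, 5, 90)
  sex <- factor(sample(c("M", "F"), n, replace = TRUE))
  # strong interaction: slope sign flips by sex
  lp <- -2.5 + ifelse(sex == "F", 0.025, -0.025) * (age - 45)
  y <- rbinom(n, 1, plogis(lp))
  fr <- data.table::data.table(outcome_fatal = y, age_years = age, sex = sex)
  out <- interaction_test(fr, "outcome_fatal", "age_years", "sex")
  expect_lt(out$p_value, 0.01)
  # no interaction
  lp0 <- -2.5 + 0.02 * (age - 45)
  fr0 <- data.table::data.table(outcome_fatal = rbinom(n, 1, plogis(lp0)),
                                age_years = age, sex = sex)
  out0 <- interaction_test(fr0, "outcome_fatal", "age_years", "sex")
  expect_gt(out0$p_value, 0.01)
  # identical data in both sexes: statistic ~ 0
  fr_dup <- rbind(data.table::data.table(outcome_fatal = fr0$outcome_fatal,
                                         age_years = age, sex = "M"),
                  data.table::data.table(outcome_fatal = fr0$outcome_fatal,
                                         age_years = age, sex = "F"))
  fr_dup$sex <- factor(fr_dup$sex)
  out_dup <- interaction_test(fr_dup, "outcome_fatal", "age_years", "sex")
  expect_gt(out_dup$p_value, 0.99)
})

test_that("stratified ORs apply the continuity correction exactly as stated", {
  # (0,10,5,100): corrected cells (0.5,10.5,5.5,100.5)
  fr <- data.table::data.table(
    outcome_fatal = c(rep(1, 0), rep(0, 10), rep(1, 5), rep(0, 100)),
    exposed = c(rep(1, 10), rep(0, 105)),
    stratum = "all")
  out <- stratified_or(fr, "outcome_fatal", "exposed", "stratum")
  expect_true(out$corrected)
  expect_equal(out$or, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(round(out$or, 4), 0.8701)
  # Fisher p computed on the uncorrected cells
  expect_equal(out$fisher_p,
               fisher.test(matrix(c(0, 10, 5, 100), 2, byrow = TRUE))$p.value)
  # no zero cells: correction off, OR is the plain cross ratio
  fr2 <- data.table::data.table(
    outcome_fatal = c(rep(1, 4), rep(0, 6), rep(1, 3), rep(0, 20)),
    exposed = c(rep(1, 10), rep(0, 23)),
    stratum = "all")
  out2 <- stratified_or(fr2, "outcome_fatal", "exposed", "stratum")
  expect_false(out2$corrected)
  expect_equal(out2$or, (4 * 20) / (6 * 3), tolerance = 1e-12)
})

test_that("crude rates and relative risk reproduce the ratio arithmetic", {
  out <- crude_rates_and_rr(433, 10000, 634, 10000)
  expect_equal(round(out$rr, 2), 0.68)
  expect_equal(out$rate_a, 0.0433)
  # symmetry
  swapped <- crude_rates_and_rr(634, 10000, 433, 10000)
  expect_equal(out$rr * swapped$rr, 1, tolerance = 1e-12)
  # equal rates
  expect_equal(crude_rates_and_rr(50, 1000, 100, 2000)$rr, 1)
  expect_false(crude_rates_and_rr(0, 1000, 10, 1000)$estimable)
})

test_that("analysis frame derives quarters and bins as specified", {
  rows <- list(
    fx_report("101", event = "20200213", age = "80", age_cod = "YR",
              sex = "F", wt = "44", wt_cod = "KG", outc = "DE",
              ther = data.frame(seq = "1", start = "20200105")),
    fx_report("201", age = "17", age_cod = "YR", wt = "90", wt_cod = "KG",
              ther = data.frame(seq = "1", start = "20201115"),
              pts = "Headache"))
  fr <- build_analysis_frame(assemble_fixture(rows))
  r1 <- fr[fr$primaryid == "101", ]
  expect_equal(r1$outcome_fatal, 1L)
  expect_equal(r1$outcome_cirvi, 1L)
  expect_equal(as.character(r1$quarter), "Q1")
  expect_equal(as.character(r1$age_bin), ">=75")
  expect_equal(as.character(r1$weight_bin), "<45")
  r2 <- fr[fr$primaryid == "201", ]
  expect_equal(r2$outcome_cirvi, 0L)
  expect_equal(as.character(r2$quarter), "Q4")
  expect_equal(as.character(r2$age_bin), "<18")
  expect_equal(as.character(r2$weight_bin), ">=80")
})
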