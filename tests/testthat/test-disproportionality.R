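# Oracle helpers, independent of the implementation path -------------------

oracle_ror <- function(t) {
  cc <- if (min(t$a, t$b, t$c, t$d) == 0) 0.5 else 0
  a <- t$a + cc; b <- t$b + cc; c <- t$c + cc; d <- t$d + cc
  est <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est, exp(log(est) - 1.96 * se), exp(log(est) + 1.96 * se))
}

oracle_yates <- function(t) {
  o <- c(t$a, t$b, t$c, t$d)
  e <- c((t$a + t$b) * (t$a + t$c), (t$a + t$b) * (t$b + t$d),
         (t$c + t$d) * (t$a + t$c), (t$c + t$d) * (t$b + t$d)) / t$N
  sum((abs(o - e) - 0.5)^2 / e)
}

# two-sided Fisher by exhaustive enumeration over tables with fixed margins
oracle_fisher <- function(t) {
  m1 <- t$a + t$b; m2 <- t$c + t$d; k <- t$a + t$c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(t$a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("2x2 construction counts each report once at report level", {
  cases <- assemble_fixture(list(
    fx_report("101", pts = c("Influenza", "Viral infection")),  # drug+event (two PTs)
    fx_report("102", pts = "Headache"),                         # drug only
    fx_report("103", drugname = "warfarin", ai = "warfarin",
              pts = "Influenza"),                               # event only
    fx_report("104", drugname = "warfarin", ai = "warfarin",
              pts = "Nausea")),                                 # neither
    keep_unmatched = TRUE)
  t <- build_table(cases, function(d) d$drug_class != "other",
                   cirvi_viral_pts())
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_error(build_table(cases[0], function(d) TRUE, "x"), "empty")
})

test_that("table margins equal an independently tallied brute-force count", {
  sh <- shared_cohort()
  cases <- sh$sim$cases
  set.seed(5)
  idx <- sample(nrow(cases), 400)
  sub <- cases[idx]
  class(sub) <- class(cases)
  t <- build_table(sub, function(d) d$drug_class == "C5", "Influenza")
  # brute force tally, loop-style
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(sub))) {
    expo <- sub$drug_class[i] == "C5"
    ev <- "Influenza" %in% sub$reaction_pts[[i]]
    if (expo && ev) a <- a + 1L else if (expo) b <- b + 1L
    else if (ev) c_ <- c_ + 1L else d <- d + 1L
  }
  expect_equal(c(t$a, t$b, t$c, t$d), c(a, b, c_, d))
})

test_that("ROR point estimates and flags follow the published criterion", {
  r <- ror(contingency(10, 20, 30, 240))
  expect_equal(r$estimate, 4.0)
  r2 <- ror(contingency(5, 5, 5, 5))
  expect_equal(r2$estimate, 1.0)
  expect_false(r2$flag)
  # hand evaluation of the CI rule at (3,1,1,3)
  lower <- exp(log(9) - 1.96 * sqrt(1 / 3 + 1 + 1 + 1 / 3))
  r3 <- ror(contingency(3, 1, 1, 3))
  expect_equal(r3$ci_low, lower, tolerance = 1e-12)
  expect_equal(r3$flag, lower > 1)
})

test_that("PRR and Yates chi-square match direct formula evaluation", {
  pc <- prr_chi2(contingency(10, 20, 30, 240))
  expect_equal(pc$prr$estimate, 3.0)
  pc0 <- prr_chi2(contingency(5, 5, 5, 5))
  expect_false(pc0$prr$flag)
  expect_false(pc0$chi2$flag)
  expect_equal(pc0$chi2$estimate, oracle_yates(contingency(5, 5, 5, 5)))
})

test_that("ROR/PRR/chi2/O-E agree with formula oracles on random tables", {
  tabs <- random_tables(300, seed = 11)
  for (t in tabs) {
    o <- oracle_ror(t)
    r <- ror(t)
    if (!is.na(r$estimate)) {
      expect_equal(c(r$estimate, r$ci_low, r$ci_high), o, tolerance = 1e-10)
    }
    pc <- prr_chi2(t)
    if (!is.na(pc$chi2$estimate)) {
      expect_equal(pc$chi2$estimate, oracle_yates(t), tolerance = 1e-10)
    }
    if (t$a > 0) {
      oe <- obs_exp(t)
      expect_equal(oe$estimate, log2(t$a / t$E), tolerance = 1e-10)
      expect_equal(oe$ci_low, oe$estimate - 1.96 / (log(2) * sqrt(t$a)),
                   tolerance = 1e-10)
    }
  }
})

test_that("row-swap symmetry maps ROR and PRR to reciprocals", {
  tabs <- random_tables(50, seed = 13)
  for (t in tabs) {
    if (min(t$a, t$b, t$c, t$d) == 0) next
    sw <- contingency(t$c, t$d, t$a, t$b)
    expect_equal(ror(sw)$estimate, 1 / ror(t)$estimate, tolerance = 1e-10)
    expect_equal(prr_chi2(sw)$prr$estimate, 1 / prr_chi2(t)$prr$estimate,
                 tolerance = 1e-10)
  }
})

test_that("Fisher p equals exhaustive enumeration and extreme closed forms", {
  expect_equal(fisher(contingency(5, 5, 5, 5))$p_value, 1, tolerance = 1e-12)
  expect_equal(fisher(contingency(10, 0, 0, 10))$p_value, 2 / choose(20, 10),
               tolerance = 1e-9)
  # all tables with N <= 15
  for (N in 1:15) {
    for (a in 0:N) for (b in 0:(N - a)) for (c_ in 0:(N - a - b)) {
      d <- N - a - b - c_
      t <- contingency(a, b, c_, d)
      expect_equal(fisher(t)$p_value, oracle_fisher(t), tolerance = 1e-9)
    }
  }
})

test_that("observed-to-expected behaves at the null and shrinks its CI", {
  t_null <- contingency(10, 90, 10, 90)
  r <- obs_exp(t_null)
  expect_equal(r$estimate, 0)
  expect_false(r$flag)
  r2 <- obs_exp(contingency(40, 60, 10, 90))
  expect_equal(r2$estimate, log2(1.6), tolerance = 1e-12)
  widths <- vapply(c(10, 40, 160, 640), function(a) {
    t <- contingency(a, 9 * a, a, 189 * a)  # a/E fixed
    r <- obs_exp(t)
    r$ci_high - r$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("BCPNN normal approximation behaves at zero counts and independence", {
  expect_lt(bcpnn_normal(contingency(0, 10, 10, 1000))$estimate, 0)
  # independence-structured large table: IC -> 0
  t <- contingency(1000, 99000, 9000, 891000)  # E = 1e5*1e4/1e6 = 1000
  expect_lt(abs(bcpnn_normal(t)$estimate), 0.05)
  # IC025 strictly below the posterior mean
  for (t in random_tables(30, seed = 17)) {
    r <- bcpnn_normal(t)
    expect_lt(r$ci_low, r$estimate)
  }
})

test_that("BCPNN Monte Carlo is seeded, symmetric at the null, and converges to the normal form", {
  t <- contingency(50, 50, 50, 50)
  r1 <- bcpnn_mc(t, draws = 50000, seed = 42)
  r2 <- bcpnn_mc(t, draws = 50000, seed = 42)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_lt(r1$ci_low, 0)
  expect_lt(abs(r1$estimate), 0.05)
  # convergence regime: report-scale tables (drug-by-PT pairs with a >= 20
  # from a cohort-sized screen); at tiny N the two published priors differ
  # and no such agreement is expected
  tabs <- mgps_grid_tables(shared_cohort()$sim$cases)
  tabs <- tabs[vapply(tabs, function(t) t$a, 0) >= 20]
  set.seed(41)
  for (t in tabs[sample(length(tabs), 25)]) {
    mc <- bcpnn_mc(t, draws = 200000, seed = 7)
    nr <- bcpnn_normal(t)
    expect_lt(abs(mc$ci_low - nr$ci_low), 0.15)
  }
})

test_that("MGPS fit ascends from the standard start and recovers a planted mixture", {
  set.seed(21)
  n <- 5000
  E <- stats::runif(n, 0.5, 20)
  comp <- stats::runif(n) < 0.4
  lam <- ifelse(comp, stats::rgamma(n, 1, 1), stats::rgamma(n, 4, 2))
  a <- stats::rpois(n, lam * E)
  tabs <- lapply(seq_len(n), function(i) {
    structure(list(a = a[i], b = 10, c = 10, d = 10, N = a[i] + 30, E = E[i]),
              class = "cirvi_table")
  })
  h <- mgps_fit(tabs)
  expect_gte(h$loglik, h$loglik_start)
  h_true <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 4, beta2 = 2,
                           w = 0.4), class = "cirvi_mgps")
  probe <- list(c(1, 1), c(5, 2), c(10, 5), c(20, 4), c(50, 10))
  for (pe in probe) {
    t <- structure(list(a = pe[1], b = 1, c = 1, d = 1, N = pe[1] + 3,
                        E = pe[2]), class = "cirvi_table")
    expect_equal(ebgm_score(t, h)$estimate, ebgm_score(t, h_true)$estimate,
                 tolerance = 0.10)
  }
})

test_that("EBGM percentiles are ordered, shrink toward the prior, and hit the large-count limit", {
  h <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 4, beta2 = 2, w = 0.4),
                 class = "cirvi_mgps")
  for (t in random_tables(20, seed = 23)) {
    if (t$E <= 0) next
    r <- ebgm_score(t, h)
    expect_lt(r$ci_low, r$estimate)
    expect_lt(r$estimate, r$ci_high)
  }
  # zero observed co-reports: EBGM below the prior mean rate
  t0 <- structure(list(a = 0, b = 10, c = 10, d = 100, N = 120, E = 5),
                  class = "cirvi_table")
  prior_mean <- 0.4 * 1 / 1 + 0.6 * 4 / 2
  expect_lt(ebgm_score(t0, h)$estimate, prior_mean)
  # large-count limit: a/E = 5 recovered within 5%
  tL <- structure(list(a = 5000, b = 1, c = 1, d = 1, N = 5003, E = 1000),
                  class = "cirvi_table")
  expect_equal(ebgm_score(tL, h)$estimate, 5, tolerance = 0.05)
  # shrinkage: |ln EBGM| <= |ln(a/E)| when a/E and prior mean sit above 1
  for (a in c(5, 15, 40, 90)) {
    t <- structure(list(a = a, b = 1, c = 1, d = 1, N = a + 3, E = a / 3),
                   class = "cirvi_table")
    expect_lte(abs(log(ebgm_score(t, h)$estimate)), abs(log(3)) + 1e-9)
  }
})

test_that("flags are pure functions of the stored result fields", {
  h <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 4, beta2 = 2, w = 0.4),
                 class = "cirvi_mgps")
  for (t in random_tables(60, seed = 29)) {
    r <- ror(t)
    if (!is.na(r$ci_low)) expect_equal(r$flag, r$ci_low > 1 && t$a >= 3)
    pc <- prr_chi2(t)
    if (!is.na(pc$chi2$estimate)) {
      expect_equal(pc$chi2$flag,
                   t$a >= 3 && pc$chi2$prr >= 2 && pc$chi2$estimate >= 4)
    }
    f <- fisher(t)
    expect_equal(f$flag, f$p_value < 0.05 && t$a >= 3)
    if (t$E > 0) {
      e <- ebgm_score(t, h)
      expect_equal(e$flag, e$ci_low > 2 && t$a >= 3)
    }
  }
})

test_that("null drug-event pairs rarely trip the ROR flag", {
  set.seed(31)
  N <- 100000; n1 <- 2000; m1 <- 250  # E = 5
  flags <- vapply(seq_len(1000), function(i) {
    a <- min(stats::rpois(1, 5), 200)
    t <- contingency(a, n1 - a, m1 - a, N - n1 - m1 + a)
    ror(t)$flag
  }, logical(1))
  expect_lte(mean(flags), 0.075)
})

test_that("a strongly planted pair flags on all methods; a=2 never flags the frequency-gated ones", {
  h <- structure(list(alpha1 = 0.5, beta1 = 0.5, alpha2 = 2, beta2 = 2,
                      w = 0.5), class = "cirvi_mgps")
  strong <- contingency(60, 940, 500, 48500)  # E ~ 10.1 in N = 50000
  p <- run_panel(h = h, seed = 3, draws = 20000, table = strong)
  expect_true(all(vapply(p$results, function(r) r$flag, logical(1))))
  null_t <- contingency(10, 990, 500, 48500)  # a close to E
  p0 <- run_panel(h = h, seed = 3, draws = 20000, table = null_t)
  for (m in c("ROR", "PRR", "BCPNN_NORM", "BCPNN_MC", "EBGM")) {
    expect_false(p0$results[[m]]$flag)
  }
  small <- contingency(2, 8, 5, 10000)  # huge disproportionality, a = 2
  p2 <- run_panel(h = h, seed = 3, draws = 20000, table = small)
  expect_false(p2$results$ROR$flag)
  expect_false(p2$results$PRR$flag)
  expect_false(p2$results$CHI2$flag)
})
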