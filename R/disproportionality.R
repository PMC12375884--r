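# Disproportionality statistics on report-level 2x2 contingency tables.
#
# The 2x2 table for a drug set D and event set V counts reports:
#       a = D & V,  b = D & !V,  c = !D & V,  d = !D & !V,  N = a+b+c+d
# with expected co-report count E = (a+b)(a+c)/N under independence.
#
# Eight methods are provided, each returning a point estimate, 95%
# interval, p-value where applicable, and a boolean signal flag computed by
# the method's published criterion:
#   ROR      lower CI > 1 and a >= 3
#   PRR      lower CI > 1 and a >= 3
#   CHI2     a >= 3, PRR >= 2, Yates chi-square >= 4
#   FISHER   two-sided p < 0.05 and a >= 3
#   OE       log2(a/E) with lower CI > 0 and a >= 3
#   BCPNN_NORM / BCPNN_MC   IC025 > 0 and a >= 3
#   EBGM     EB05 (5th posterior percentile) > 2 and a >= 3

#' Build a 2x2 contingency table from case reports
#'
#' Report-level counting: a report is in the event margin iff any of its
#' reaction PTs satisfies `event_filter`; each report counts once.
#'
#' @param reports A `cirvi_cases` table (complement and background reports).
#' @param drug_filter Function of the reports table returning a logical
#'   vector (TRUE = exposed row), or a logical vector directly.
#' @param event_filter Function of one PT character vector returning TRUE if
#'   the report qualifies as an event, or a character vector of PTs
#'   (interpreted as "any of these PTs").
#' @return A `cirvi_table` list with fields `a`, `b`, `c`, `d`, `N`, `E`.
#' @export
build_table <- function(reports, drug_filter, event_filter) {
  dt <- data.table::as.data.table(reports)
  if (nrow(dt) == 0) stop("build_table: empty report list")
  exposed <- if (is.function(drug_filter)) drug_filter(dt) else as.logical(drug_filter)
  stopifnot(length(exposed) == nrow(dt))
  event <- report_has_event(dt, event_filter)
  contingency(sum(exposed & event), sum(exposed & !event),
              sum(!exposed & event), sum(!exposed & !event))
}

#' Test which reports carry a qualifying event
#' @param reports `cirvi_cases` table.
#' @param event_filter As in [build_table()].
#' @return Logical vector, one element per report.
#' @export
report_has_event <- function(reports, event_filter) {
  if (is.character(event_filter)) {
    evset <- event_filter
    event_filter <- function(pts) any(pts %in% evset)
  }
  vapply(reports$reaction_pts, function(p) isTRUE(event_filter(p)), logical(1))
}

#' Construct a contingency table from the four counts
#' @param a,b,c,d Non-negative integer counts.
#' @return A `cirvi_table` with derived `N` and `E`.
#' @export
contingency <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency cells must be non-negative integers")
  }
  # doubles throughout: margin products overflow 32-bit integers at
  # database scale
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  if (N <= 0) stop("contingency table is empty (N = 0)")
  structure(list(a = a, b = b, c = c, d = d, N = N,
                 E = (a + b) * (a + c) / N),
            class = "cirvi_table")
}

#' @export
print.cirvi_table <- function(x, ...) {
  cat(sprintf("<cirvi_table> a=%g b=%g c=%g d=%g (N=%g, E=%.3f)\n",
              x$a, x$b, x$c, x$d, x$N, x$E))
  invisible(x)
}

.method_result <- function(method, estimate, ci_low, ci_high, p_value, flag,
                           extra = NULL) {
  structure(c(list(method = method, estimate = estimate, ci_low = ci_low,
                   ci_high = ci_high, p_value = p_value,
                   flag = isTRUE(flag)), extra),
            class = "cirvi_method_result")
}

#' @export
print.cirvi_method_result <- function(x, ...) {
  cat(sprintf("%s: %.4g [%.4g, %.4g]%s flag=%s\n", x$method, x$estimate,
              x$ci_low, x$ci_high,
              if (is.na(x$p_value)) "" else sprintf(" p=%.3g", x$p_value),
              x$flag))
  invisible(x)
}

# Haldane-Anscombe: +0.5 to every cell, applied only when a zero cell exists
.haldane <- function(t) {
  if (min(t$a, t$b, t$c, t$d) > 0) return(t)
  structure(list(a = t$a + 0.5, b = t$b + 0.5, c = t$c + 0.5, d = t$d + 0.5,
                 N = t$N + 2, E = (t$a + t$b + 1) * (t$a + t$c + 1) / (t$N + 2)),
            class = "cirvi_table")
}

#' Reporting odds ratio
#'
#' ROR = ad/(bc) with Woolf (log-scale Wald) 95% CI. When a zero cell is
#' present, the Haldane-Anscombe +0.5 correction is applied to all cells for
#' the estimate and CI. Signal: lower CI > 1 and a >= 3.
#'
#' @param t A `cirvi_table`.
#' @return A `cirvi_method_result`.
#' @export
ror <- function(t) {
  h <- .haldane(t)
  if (min(h$a + h$b, h$c + h$d, h$a + h$c, h$b + h$d) == 0) {
    return(.method_result("ROR", NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  }
  est <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  ci <- exp(log(est) + c(-1, 1) * 1.96 * se)
  .method_result("ROR", est, ci[1], ci[2], NA_real_,
                 ci[1] > 1 && t$a >= 3)
}

#' Proportional reporting ratio and Yates chi-square
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\] with log-scale Wald CI; chi-square is the
#' Yates-corrected Pearson statistic (sum of (|O-E|-0.5)^2/E over the four
#' cells). PRR signal: lower CI > 1 and a >= 3. Chi-square signal: a >= 3,
#' PRR >= 2 and chi-square >= 4.
#'
#' @param t A `cirvi_table`.
#' @return List with elements `prr` and `chi2`, both `cirvi_method_result`.
#' @export
prr_chi2 <- function(t) {
  h <- .haldane(t)
  if ((h$a + h$b) == 0 || (h$c + h$d) == 0 || h$c == 0) {
    und <- .method_result("PRR", NA_real_, NA_real_, NA_real_, NA_real_, FALSE)
    return(list(prr = und,
                chi2 = .method_result("CHI2", NA_real_, NA_real_, NA_real_, NA_real_, FALSE)))
  }
  prr <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  se <- sqrt(1 / h$a - 1 / (h$a + h$b) + 1 / h$c - 1 / (h$c + h$d))
  ci <- exp(log(prr) + c(-1, 1) * 1.96 * se)
  prr_res <- .method_result("PRR", prr, ci[1], ci[2], NA_real_,
                            ci[1] > 1 && t$a >= 3)
  # chi-square on the original (uncorrected) counts
  obs <- c(t$a, t$b, t$c, t$d)
  rows <- c(t$a + t$b, t$c + t$d)
  cols <- c(t$a + t$c, t$b + t$d)
  expd <- c(rows[1] * cols[1], rows[1] * cols[2],
            rows[2] * cols[1], rows[2] * cols[2]) / t$N
  if (any(expd == 0)) {
    chi2_res <- .method_result("CHI2", NA_real_, NA_real_, NA_real_, NA_real_, FALSE)
  } else {
    stat <- sum((abs(obs - expd) - 0.5)^2 / expd)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    chi2_res <- .method_result("CHI2", stat, NA_real_, NA_real_, p,
                               t$a >= 3 && prr >= 2 && stat >= 4,
                               extra = list(prr = prr))
  }
  list(prr = prr_res, chi2 = chi2_res)
}

#' Fisher's exact test (two-sided)
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. Signal:
#' p < 0.05 and a >= 3. Always computed on the original counts.
#'
#' @param t A `cirvi_table`.
#' @return A `cirvi_method_result`; `estimate` is the sample odds ratio
#'   ad/(bc) (not the conditional MLE).
#' @export
fisher <- function(t) {
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  est <- if (t$b * t$c > 0) (t$a * t$d) / (t$b * t$c) else NA_real_
  .method_result("FISHER", est, NA_real_, NA_real_, p,
                 p < 0.05 && t$a >= 3)
}

#' Observed-to-expected ratio on the log2 scale
#'
#' Estimate log2(a/E) with Wald CI of half-width 1.96/(ln 2 * sqrt(a)).
#' Signal: lower CI > 0 and a >= 3.
#'
#' @param t A `cirvi_table`.
#' @return A `cirvi_method_result`.
#' @export
obs_exp <- function(t) {
  if (t$a == 0 || t$E == 0) {
    return(.method_result("OE", NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  }
  est <- log2(t$a / t$E)
  half <- 1.96 / (log(2) * sqrt(t$a))
  .method_result("OE", est, est - half, est + half, NA_real_,
                 (est - half) > 0 && t$a >= 3)
}

#' BCPNN information component, closed-form normal approximation
#'
#' Posterior mean and variance of the information component
#' IC = log2 p11/(p1. p.1) under the standard prior
#' (alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1 with gamma scaled for
#' prior independence). IC025 = E\[IC\] - 1.96 sd. Signal: IC025 > 0 and
#' a >= 3.
#'
#' @param t A `cirvi_table`.
#' @return A `cirvi_method_result` with `estimate` = posterior mean IC.
#' @export
bcpnn_normal <- function(t) {
  a <- t$a; N <- t$N
  n1 <- t$a + t$b   # drug margin
  m1 <- t$a + t$c   # event margin
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (N + al) * (N + be) / ((n1 + a1) * (m1 + b1))
  eic <- log2((a + g11) * (N + al) * (N + be) /
                ((N + g) * (n1 + a1) * (m1 + b1)))
  vic <- ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
            (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
            (N - m1 + be - b1) / ((m1 + b1) * (1 + N + be))) / log(2)^2
  ic025 <- eic - 1.96 * sqrt(vic)
  .method_result("BCPNN_NORM", eic, ic025, eic + 1.96 * sqrt(vic), NA_real_,
                 ic025 > 0 && a >= 3)
}

#' BCPNN information component by Monte Carlo simulation
#'
#' Simulates the Dirichlet(1+a, 1+b, 1+c, 1+d) posterior on the four cell
#' probabilities; per draw IC = log2 p11/((p11+p10)(p11+p01)). IC025 is the
#' empirical 2.5th percentile. Deterministic given `seed`. Signal:
#' IC025 > 0 and a >= 3.
#'
#' @param t A `cirvi_table`.
#' @param draws Number of posterior draws (>= 1000).
#' @param seed Integer seed (required for reproducibility).
#' @return A `cirvi_method_result` with `estimate` = posterior median IC.
#' @export
bcpnn_mc <- function(t, draws = 100000L, seed) {
  stopifnot(draws >= 1000)
  if (!missing(seed) && !is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  g <- matrix(stats::rgamma(4L * draws,
                            shape = rep(c(t$a, t$b, t$c, t$d) + 1, each = draws)),
              nrow = draws)
  s <- rowSums(g)
  p11 <- g[, 1] / s
  p1. <- (g[, 1] + g[, 2]) / s
  p.1 <- (g[, 1] + g[, 3]) / s
  ic <- log2(p11 / (p1. * p.1))
  q <- stats::quantile(ic, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  .method_result("BCPNN_MC", q[2], q[1], q[3], NA_real_,
                 q[1] > 0 && t$a >= 3, extra = list(draws = draws))
}

#' Fit the MGPS two-gamma mixture prior by marginal likelihood
#'
#' The observed count a_i of each drug-event pair is modelled as Poisson
#' with mean lambda_i * E_i, lambda_i drawn from the mixture
#' w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2). Marginally a_i is a
#' two-component negative binomial mixture; the five hyperparameters are
#' fitted by L-BFGS-B on log/logit transformed parameters from the
#' conventional start (0.2, 0.1, 2.0, 4.0, 1/3).
#'
#' @param tables List of `cirvi_table` objects (>= 20 with finite E > 0).
#' @return A `cirvi_mgps` list: `alpha1`, `beta1`, `alpha2`, `beta2`, `w`,
#'   `loglik`, `loglik_start`, `convergence`.
#' @export
mgps_fit <- function(tables) {
  a <- vapply(tables, function(t) t$a, 0)
  E <- vapply(tables, function(t) t$E, 0)
  ok <- is.finite(E) & E > 0
  a <- a[ok]; E <- E[ok]
  if (length(a) < 20) stop("mgps_fit needs at least 20 tables with E > 0")
  negll <- function(par) {
    al1 <- exp(par[1]); be1 <- exp(par[2])
    al2 <- exp(par[3]); be2 <- exp(par[4])
    w <- stats::plogis(par[5])
    f1 <- stats::dnbinom(a, size = al1, prob = be1 / (be1 + E))
    f2 <- stats::dnbinom(a, size = al2, prob = be2 / (be2 + E))
    ll <- sum(log(pmax(w * f1 + (1 - w) * f2, 1e-300)))
    -ll
  }
  start <- c(log(0.2), log(0.1), log(2.0), log(4.0), stats::qlogis(1 / 3))
  ll_start <- -negll(start)
  fit <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = rep(c(log(1e-4), -Inf), c(4, 1)),
                      upper = rep(c(log(1e4), Inf), c(4, 1)),
                      control = list(maxit = 500))
  if (-fit$value < ll_start - 1e-6) {
    stop(sprintf(paste0("mgps_fit did not improve on the starting values ",
                        "(loglik %.4f vs %.4f); best iterate: %s"),
                 -fit$value, ll_start,
                 paste(signif(fit$par, 4), collapse = ", ")))
  }
  structure(list(alpha1 = exp(fit$par[1]), beta1 = exp(fit$par[2]),
                 alpha2 = exp(fit$par[3]), beta2 = exp(fit$par[4]),
                 w = stats::plogis(fit$par[5]),
                 loglik = -fit$value, loglik_start = ll_start,
                 convergence = fit$convergence),
            class = "cirvi_mgps")
}

#' @export
print.cirvi_mgps <- function(x, ...) {
  cat(sprintf(paste0("<cirvi_mgps> alpha1=%.4g beta1=%.4g alpha2=%.4g ",
                     "beta2=%.4g w=%.3f (loglik %.2f)\n"),
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$w, x$loglik))
  invisible(x)
}

#' EBGM score under a fitted MGPS prior
#'
#' The posterior of the relative reporting rate lambda is a two-gamma
#' mixture with components Gamma(alpha_j + a, beta_j + E) and posterior
#' mixing weight Q. EBGM = exp(E\[log lambda\]) (geometric mean); EB05 is
#' the 5th posterior percentile found by bisection on the mixture CDF to
#' 1e-6. Signal: EB05 > 2 and a >= 3.
#'
#' @param t A `cirvi_table`.
#' @param h A `cirvi_mgps` fit.
#' @return A `cirvi_method_result` with `estimate` = EBGM, `ci_low` = EB05,
#'   `ci_high` = EB95.
#' @export
ebgm_score <- function(t, h) {
  a <- t$a; E <- t$E
  if (!is.finite(E) || E <= 0) stop("ebgm_score requires E > 0")
  lf1 <- stats::dnbinom(a, size = h$alpha1, prob = h$beta1 / (h$beta1 + E), log = TRUE)
  lf2 <- stats::dnbinom(a, size = h$alpha2, prob = h$beta2 / (h$beta2 + E), log = TRUE)
  lw <- log(h$w) + lf1
  l2 <- log(1 - h$w) + lf2
  m <- max(lw, l2)
  Q <- exp(lw - m) / (exp(lw - m) + exp(l2 - m))
  s1 <- h$alpha1 + a; r1 <- h$beta1 + E
  s2 <- h$alpha2 + a; r2 <- h$beta2 + E
  ebln <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(ebln)
  cdf <- function(x) Q * stats::pgamma(x, s1, rate = r1) +
    (1 - Q) * stats::pgamma(x, s2, rate = r2)
  qmix <- function(p) {
    lo <- 0
    hi <- max(stats::qgamma(p, s1, rate = r1), stats::qgamma(p, s2, rate = r2)) + 1
    while (cdf(hi) < p) hi <- hi * 2
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  eb05 <- qmix(0.05)
  eb95 <- qmix(0.95)
  .method_result("EBGM", ebgm, eb05, eb95, NA_real_,
                 eb05 > 2 && a >= 3, extra = list(Q = Q))
}

.panel_methods <- c("ROR", "PRR", "CHI2", "FISHER", "OE",
                    "BCPNN_NORM", "BCPNN_MC", "EBGM")

#' Run the eight-method signal panel on one drug-event pair
#'
#' @param reports `cirvi_cases` (exposed and background reports together).
#' @param drug_filter,event_filter As in [build_table()].
#' @param h A `cirvi_mgps` fit (from the full drug-by-PT grid).
#' @param seed Seed for the Monte Carlo BCPNN.
#' @param draws Monte Carlo draws (default 100000).
#' @param table Optionally a pre-built `cirvi_table` (then `reports` and the
#'   filters are ignored).
#' @return A `cirvi_panel`: list of eight `cirvi_method_result`s plus the
#'   table used.
#' @export
run_panel <- function(reports = NULL, drug_filter = NULL, event_filter = NULL,
                      h, seed, draws = 100000L, table = NULL) {
  t <- if (!is.null(table)) table else build_table(reports, drug_filter, event_filter)
  pc <- prr_chi2(t)
  res <- list(ROR = ror(t), PRR = pc$prr, CHI2 = pc$chi2, FISHER = fisher(t),
              OE = obs_exp(t), BCPNN_NORM = bcpnn_normal(t),
              BCPNN_MC = bcpnn_mc(t, draws = draws, seed = seed),
              EBGM = ebgm_score(t, h))
  structure(list(table = t, results = res), class = "cirvi_panel")
}

#' Tidy a panel (or list of panels) into a long table
#'
#' One row per method with estimate, interval, p, flag and the four counts.
#'
#' @param panel A `cirvi_panel`.
#' @param ... Extra constant columns (e.g. stratum, pt) prepended.
#' @return A `data.table`.
#' @export
tidy_panel <- function(panel, ...) {
  extras <- list(...)
  rows <- lapply(panel$results, function(r) {
    data.table::data.table(method = r$method, estimate = r$estimate,
                           ci_low = r$ci_low, ci_high = r$ci_high,
                           p = r$p_value, a = panel$table$a, b = panel$table$b,
                           c = panel$table$c, d = panel$table$d,
                           flag = r$flag)
  })
  out <- data.table::rbindlist(rows)
  if (length(extras) > 0) out <- cbind(data.table::as.data.table(extras), out)
  out[]
}

#' @export
print.cirvi_panel <- function(x, ...) {
  print(x$table)
  for (r in x$results) print(r)
  invisible(x)
}
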