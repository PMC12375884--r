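# Composite criterion promoting a PT to a complement-inhibitor-related
# viral infection adverse event (CIRVI-AE).
#
# A PT qualifies iff BOTH:
#  (1) the ROR flag (lower 95% CI > 1, a >= 3) holds in the overall
#      analysis AND in each class stratum (C3, C5, FactorB), and
#  (2) at least one of the eight methods flags in the overall analysis and
#      in at least two of the three class strata.
# Clause (2) is evaluated same-method-throughout by default; the
# `clause2_mode = "mixed"` reading allows different methods to supply the
# overall and stratum flags.
#
# Strata compare one inhibitor class against the non-complement background
# reports (class "other"); "overall" compares all complement classes
# against that same background, so the stratum a-cells partition the
# overall a-cell.

#' The four viral infection preferred terms
#' @export
cirvi_viral_pts <- function() {
  c("Influenza", "Herpes zoster", "Gastroenteritis viral", "Viral infection")
}

.strata <- c("overall", "C3", "C5", "FactorB")

#' Build the four stratified signal panels for one event set
#'
#' @param reports `cirvi_cases` containing complement reports and the
#'   background (`drug_class == "other"`).
#' @param event_filter PT vector or predicate, as in [build_table()].
#' @param h `cirvi_mgps` fit.
#' @param seed Seed for the Monte Carlo BCPNN.
#' @param draws Monte Carlo draws.
#' @return A `cirvi_panelset`: list with `panels` (named by stratum) where
#'   each stratum is exposed-class vs background.
#' @export
stratified_panels <- function(reports, event_filter, h, seed,
                              draws = 100000L) {
  dt <- data.table::as.data.table(reports)
  bg <- dt$drug_class == "other"
  if (!any(bg)) stop("stratified_panels: no background reports (drug_class 'other')")
  event <- report_has_event(dt, event_filter)
  panels <- lapply(.strata, function(s) {
    exposed <- if (s == "overall") dt$drug_class %in% c("C3", "C5", "FactorB")
               else dt$drug_class == s
    t <- contingency(sum(exposed & event), sum(exposed & !event),
                     sum(bg & event), sum(bg & !event))
    run_panel(h = h, seed = seed, draws = draws, table = t)
  })
  names(panels) <- .strata
  structure(list(panels = panels), class = "cirvi_panelset")
}

#' Apply the two-part CIRVI criterion to a stratified panel set
#'
#' @param s A `cirvi_panelset` (all four panels present).
#' @param clause2_mode `"same_method"` (default): one method must flag in
#'   the overall analysis and in >= 2 strata; `"mixed"`: the overall and
#'   stratum flags may come from different methods.
#' @return List: `cirvi` (logical), `clause1`, `clause2`,
#'   `clause2_methods` (methods satisfying clause 2 under same-method
#'   reading), and `evidence` (flag matrix methods x strata).
#' @export
classify_cirvi <- function(s, clause2_mode = c("same_method", "mixed")) {
  clause2_mode <- match.arg(clause2_mode)
  if (!all(.strata %in% names(s$panels)) ||
      any(vapply(s$panels[.strata], is.null, logical(1)))) {
    stop("classify_cirvi: all four stratum panels (overall, C3, C5, FactorB) are required")
  }
  flags <- vapply(.strata, function(st)
    vapply(s$panels[[st]]$results, function(r) isTRUE(r$flag), logical(1)),
    logical(length(.panel_methods)))
  rownames(flags) <- .panel_methods
  clause1 <- all(flags["ROR", ])
  sub <- c("C3", "C5", "FactorB")
  per_method <- flags[, "overall"] & rowSums(flags[, sub, drop = FALSE]) >= 2
  clause2 <- if (clause2_mode == "same_method") {
    any(per_method)
  } else {
    any(flags[, "overall"]) &&
      sum(vapply(sub, function(st) any(flags[, st]), logical(1))) >= 2
  }
  list(cirvi = clause1 && clause2,
       clause1 = clause1,
       clause2 = clause2,
       clause2_methods = names(which(per_method)),
       evidence = flags)
}

#' Screen every observed PT through the eight-method stratified analysis
#'
#' Every PT reported at least once among complement-exposed reports is
#' evaluated in the overall and three class-stratum panels and classified
#' by the composite criterion. Results are sorted by overall ROR
#' (descending).
#'
#' @param reports `cirvi_cases` with background reports present.
#' @param h `cirvi_mgps` fit; if `NULL`, fitted on the drug-by-PT grid of
#'   `reports` via [mgps_grid_fit()].
#' @param seed Integer seed.
#' @param draws Monte Carlo draws per panel (default 100000).
#' @param pooled Also screen the four viral PTs as one combined event set
#'   (row `pt = "CIRVI-AE (pooled)"`). Default `TRUE`.
#' @param clause2_mode Passed to [classify_cirvi()].
#' @return List: `summary` (data.table: pt, a/ROR per stratum, cirvi flag,
#'   clauses), `panelsets` (named list of `cirvi_panelset`).
#' @export
screen_pt_universe <- function(reports, h = NULL, seed, draws = 100000L,
                               pooled = TRUE,
                               clause2_mode = "same_method") {
  dt <- data.table::as.data.table(reports)
  exposed <- dt$drug_class %in% c("C3", "C5", "FactorB")
  if (is.null(h)) h <- mgps_grid_fit(dt)
  pts <- sort(unique(unlist(dt$reaction_pts[exposed])))
  targets <- as.list(pts)
  names(targets) <- pts
  if (pooled) targets[["CIRVI-AE (pooled)"]] <- cirvi_viral_pts()
  panelsets <- lapply(targets, function(ev)
    stratified_panels(dt, ev, h = h, seed = seed, draws = draws))
  rows <- lapply(names(panelsets), function(nm) {
    ps <- panelsets[[nm]]
    cl <- classify_cirvi(ps, clause2_mode = clause2_mode)
    row <- data.table::data.table(pt = nm)
    for (st in .strata) {
      r <- ps$panels[[st]]$results$ROR
      row[[paste0("a_", st)]] <- ps$panels[[st]]$table$a
      row[[paste0("ror_", st)]] <- r$estimate
      row[[paste0("ror_low_", st)]] <- r$ci_low
      row[[paste0("ror_high_", st)]] <- r$ci_high
    }
    row$clause1 <- cl$clause1
    row$clause2 <- cl$clause2
    row$clause2_methods <- paste(cl$clause2_methods, collapse = ",")
    row$cirvi <- cl$cirvi
    row
  })
  summary <- data.table::rbindlist(rows)
  data.table::setorder(summary, -ror_overall, na.last = TRUE)
  list(summary = summary[], panelsets = panelsets, mgps = h)
}

#' Fit the MGPS prior on the full drug-by-PT grid of a case set
#'
#' One contingency table per (PS drug, PT) pair with a >= `min_a`
#' co-reports; the a-cell margin is the drug, the event margin the PT,
#' counted at report level across the whole dataset.
#'
#' @param reports `cirvi_cases`.
#' @param min_a Minimum co-report count for a pair to enter the fit
#'   (default 1).
#' @return A `cirvi_mgps`.
#' @export
mgps_grid_fit <- function(reports, min_a = 1L) {
  mgps_fit(mgps_grid_tables(reports, min_a = min_a))
}

#' Enumerate drug-by-PT contingency tables
#' @rdname mgps_grid_fit
#' @export
mgps_grid_tables <- function(reports, min_a = 1L) {
  dt <- data.table::as.data.table(reports)
  long <- data.table::data.table(
    drug = rep(dt$ps_drug, vapply(dt$reaction_pts, length, 0L)),
    pt = unlist(dt$reaction_pts))
  pairs <- long[, .N, by = list(drug, pt)]
  drug_n <- table(dt$ps_drug)
  # report-level PT margin (reaction_pts are unique within a report)
  pt_margin <- long[, list(m = .N), by = pt]
  N <- nrow(dt)
  tabs <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$N[i]
    if (a < min_a) return(NULL)
    n1 <- as.integer(drug_n[[pairs$drug[i]]])
    m1 <- pt_margin$m[pt_margin$pt == pairs$pt[i]]
    contingency(a, n1 - a, m1 - a, N - n1 - m1 + a)
  })
  Filter(Negate(is.null), tabs)
}
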