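# Time-to-onset (TTO) analysis: days from therapy initiation to event
# onset. All identified cases experienced the event, so there is no
# censoring and the analysis is purely descriptive (medians, IQRs,
# empirical CDFs) plus nonparametric group comparisons.

#' Compute time-to-onset records
#'
#' One record per report with both `therapy_start` and `event_date`
#' present and a non-negative interval. Reports failing either condition
#' are excluded and tallied.
#'
#' @param reports `cirvi_cases`.
#' @param event_filter Optional PT vector or predicate restricting to
#'   reports carrying a qualifying reaction (e.g. the viral PTs); `NULL`
#'   keeps all reports.
#' @return A `data.table` (`primaryid`, `tto_days`, `outcome_group`,
#'   `drug_class`) with attribute `n_excluded` = list(missing, negative).
#' @export
compute_tto <- function(reports, event_filter = NULL) {
  dt <- data.table::as.data.table(reports)
  if (!is.null(event_filter)) dt <- dt[report_has_event(dt, event_filter)]
  tto <- as.integer(dt$event_date - dt$therapy_start)
  missing <- is.na(tto)
  negative <- !missing & tto < 0
  keep <- !missing & !negative
  out <- data.table::data.table(
    primaryid = dt$primaryid[keep],
    tto_days = tto[keep],
    outcome_group = data.table::fifelse(
      vapply(dt$outcomes[keep], function(o) "DE" %in% o, logical(1)),
      "fatal", "non_fatal"),
    drug_class = dt$drug_class[keep])
  data.table::setattr(out, "n_excluded",
                      list(missing = sum(missing), negative = sum(negative)))
  out[]
}

#' Per-group TTO summaries and empirical CDFs
#'
#' Medians and IQRs use linear interpolation between order statistics
#' (quantile type 7); the ECDF is reported as right-continuous step points
#' at the observed values.
#'
#' @param records Output of [compute_tto()].
#' @param grouping `"outcome_group"` or `"drug_class"`.
#' @return List: `summary` (group, n, median, q25, q75) and `ecdf`
#'   (group, t, F). Empty groups are omitted.
#' @export
summarize_tto <- function(records, grouping = c("outcome_group", "drug_class")) {
  grouping <- match.arg(grouping)
  dt <- data.table::as.data.table(records)
  summary <- dt[, list(
    n = .N,
    median = stats::quantile(tto_days, 0.5, type = 7, names = FALSE),
    q25 = stats::quantile(tto_days, 0.25, type = 7, names = FALSE),
    q75 = stats::quantile(tto_days, 0.75, type = 7, names = FALSE)
  ), by = grouping]
  ecdf_pts <- dt[, {
    t_sorted <- sort(unique(tto_days))
    list(t = t_sorted, F = stats::ecdf(tto_days)(t_sorted))
  }, by = grouping]
  data.table::setnames(summary, grouping, "group")
  data.table::setnames(ecdf_pts, grouping, "group")
  list(summary = summary[], ecdf = ecdf_pts[])
}

#' Nonparametric comparison of TTO across groups
#'
#' Kruskal-Wallis for three or more groups, Wilcoxon rank-sum for two;
#' pairwise follow-up comparisons are Benjamini-Hochberg adjusted. If every
#' value is tied within and across groups, p = 1 with a degeneracy note.
#'
#' @param records Output of [compute_tto()].
#' @param grouping `"outcome_group"` or `"drug_class"`.
#' @return List: `test` (name), `statistic`, `p_value`, `pairwise`
#'   (data.table of BH-adjusted pairwise p-values; `NULL` for two groups),
#'   `note`.
#' @export
compare_tto_groups <- function(records, grouping = c("outcome_group", "drug_class")) {
  grouping <- match.arg(grouping)
  dt <- data.table::as.data.table(records)
  g <- factor(dt[[grouping]])
  if (nlevels(g) < 2) stop("compare_tto_groups needs at least two groups")
  if (length(unique(dt$tto_days)) == 1) {
    return(list(test = "degenerate", statistic = NA_real_, p_value = 1,
                pairwise = NULL, note = "all values tied"))
  }
  if (nlevels(g) == 2) {
    wt <- stats::wilcox.test(tto_days ~ g, data = dt, exact = FALSE)
    return(list(test = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value, pairwise = NULL, note = NULL))
  }
  kw <- stats::kruskal.test(dt$tto_days, g)
  combos <- utils::combn(levels(g), 2)
  praw <- apply(combos, 2, function(pair) {
    stats::wilcox.test(dt$tto_days[g == pair[1]], dt$tto_days[g == pair[2]],
                       exact = FALSE)$p.value
  })
  pairwise <- data.table::data.table(group1 = combos[1, ], group2 = combos[2, ],
                                     p_raw = praw,
                                     p_adj = stats::p.adjust(praw, "BH"))
  list(test = "kruskal-wallis", statistic = unname(kw$statistic),
       p_value = kw$p.value, pairwise = pairwise, note = NULL)
}
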