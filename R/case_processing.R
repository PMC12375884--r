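# Deduplication and exclusion protocol for assembled case reports.
#
# Stages, in the order run_processing() applies them:
#   1. dedupe_by_case      - one report per CASEID (latest FDA_DT, then
#                            highest PRIMARYID)
#   2. apply_deletion_list - FDA quarterly deletion lists
#   3. dedupe_by_content   - identical key fields across different CASEIDs
#   4. screen_validity     - minimal validity criteria
#   5. exclude_prior_anti_infective - systemic anti-infective started within
#                            14 days before complement-inhibitor initiation
# Every removed report is logged once with exactly one reason, so
# |kept| + |removed| = |input| at each stage.

.exclusion_log <- function(primaryid, reason) {
  data.table::data.table(primaryid = as.character(primaryid), reason = reason)
}

.pid_num <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) rank(x, ties.method = "first") else n
}

#' Keep one report version per CASEID
#'
#' For records sharing a CASEID, retains the one with the most recent
#' FDA_DT; on ties, the one with the highest PRIMARYID.
#'
#' @param reports A `cirvi_cases` table.
#' @return `list(kept = <cases>, removed = <exclusion log>)` with reason
#'   `superseded_caseid`.
#' @export
dedupe_by_case <- function(reports) {
  dt <- data.table::as.data.table(reports)
  if (nrow(dt) == 0) return(list(kept = reports, removed = .exclusion_log(character(0), character(0))))
  ord <- order(dt$caseid, dt$fda_date, .pid_num(dt$primaryid), decreasing = TRUE)
  ranked <- dt[ord]
  keep_pid <- ranked[!duplicated(caseid)]$primaryid
  kept <- dt[primaryid %in% keep_pid]
  removed <- .exclusion_log(setdiff(dt$primaryid, keep_pid), "superseded_caseid")
  class(kept) <- class(reports)
  list(kept = kept, removed = removed)
}

#' Content-based deduplication
#'
#' Among reports (already unique per CASEID) sharing identical key fields —
#' sex, age (1 decimal), country, event date, sorted reaction PT list, PS
#' drug and sorted indication list — the one with the highest PRIMARYID is
#' kept. Reports with any missing key field are never matched: collapsing
#' on shared missingness would merge genuinely distinct reports.
#'
#' @param reports A `cirvi_cases` table.
#' @return `list(kept, removed)` with reason `content_duplicate`.
#' @export
dedupe_by_content <- function(reports) {
  dt <- data.table::as.data.table(reports)
  if (nrow(dt) == 0) return(list(kept = reports, removed = .exclusion_log(character(0), character(0))))
  key <- paste(
    dt$sex,
    formatC(round(dt$age_years, 1), format = "f", digits = 1),
    dt$country,
    as.character(dt$event_date),
    vapply(dt$reaction_pts, function(p) paste(sort(p), collapse = "|"), ""),
    dt$ps_drug,
    vapply(dt$indications, function(p) paste(sort(p), collapse = "|"), ""),
    sep = "\r"
  )
  eligible <- !is.na(dt$age_years) & !is.na(dt$event_date) &
    dt$sex != "unknown" & nzchar(dt$country)
  key[!eligible] <- paste0("uniq\r", dt$primaryid[!eligible])
  ord <- order(key, .pid_num(dt$primaryid), decreasing = TRUE)
  keep_pid <- dt[ord][!duplicated(key[ord])]$primaryid
  kept <- dt[primaryid %in% keep_pid]
  removed <- .exclusion_log(setdiff(dt$primaryid, keep_pid), "content_duplicate")
  class(kept) <- class(reports)
  list(kept = kept, removed = removed)
}

#' Remove reports withdrawn via FDA deletion lists
#'
#' @param reports A `cirvi_cases` table.
#' @param deleted_caseids Character vector (duplicates tolerated) of CASEIDs
#'   to drop.
#' @return `list(kept, removed)` with reason `deleted_by_fda`.
#' @export
apply_deletion_list <- function(reports, deleted_caseids) {
  dt <- data.table::as.data.table(reports)
  drop <- dt$caseid %in% unique(as.character(deleted_caseids))
  kept <- dt[!drop]
  class(kept) <- class(reports)
  list(kept = kept, removed = .exclusion_log(dt$primaryid[drop], "deleted_by_fda"))
}

#' Screen out invalid reports
#'
#' A report is invalid iff it lacks a primary-suspect complement inhibitor
#' (when `require_complement`) or has an empty reaction list.
#'
#' @param reports A `cirvi_cases` table.
#' @param require_complement Require `drug_class` in C3/C5/FactorB. Set
#'   `FALSE` when background (non-complement) reports are being retained as
#'   disproportionality denominators.
#' @return `list(kept, removed)` with reason `invalid`.
#' @export
screen_validity <- function(reports, require_complement = TRUE) {
  dt <- data.table::as.data.table(reports)
  bad <- vapply(dt$reaction_pts, length, 0L) == 0
  if (require_complement) {
    bad <- bad | !(dt$drug_class %in% c("C3", "C5", "FactorB"))
  }
  kept <- dt[!bad]
  class(kept) <- class(reports)
  list(kept = kept, removed = .exclusion_log(dt$primaryid[bad], "invalid"))
}

#' Exclude reports with recent prior systemic anti-infective therapy
#'
#' A report is removed iff some concomitant drug matches the anti-infective
#' name list and started on day d with
#' `therapy_start - window_days <= d < therapy_start` (day −window inclusive,
#' initiation day exclusive). Missing dates retain the report: exclusion
#' requires positive evidence of the overlap.
#'
#' @param reports A `cirvi_cases` table.
#' @param anti_infective_names Character vector of drug names (case and
#'   whitespace insensitive).
#' @param window_days Look-back window in days (default 14).
#' @return `list(kept, removed)` with reason `prior_anti_infective`.
#' @export
exclude_prior_anti_infective <- function(reports, anti_infective_names,
                                         window_days = 14L) {
  dt <- data.table::as.data.table(reports)
  ai <- unique(.norm_name(anti_infective_names))
  hit <- logical(nrow(dt))
  candidates <- which(!is.na(dt$therapy_start) &
                        !vapply(dt$concomitant, is.null, logical(1)))
  for (i in candidates) {
    ts <- dt$therapy_start[i]
    con <- dt$concomitant[[i]]
    if (nrow(con) == 0) next
    j <- con$name %in% ai & !is.na(con$start_date)
    if (!any(j)) next
    d <- con$start_date[j]
    hit[i] <- any(d >= ts - window_days & d < ts)
  }
  kept <- dt[!hit]
  class(kept) <- class(reports)
  list(kept = kept, removed = .exclusion_log(dt$primaryid[hit], "prior_anti_infective"))
}

#' Read a one-entry-per-line plain-text list
#'
#' Used for FDA deletion lists (CASEIDs) and anti-infective name lists.
#'
#' @param path File path; `NULL` yields an empty vector.
#' @return Character vector, comments (#) and blank lines stripped.
#' @export
read_line_list <- function(path) {
  if (is.null(path) || is.na(path) || !nzchar(path)) return(character(0))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Run the full processing chain
#'
#' Applies the five stages in protocol order and accumulates the exclusion
#' log. Idempotent: re-running on the kept set removes nothing further.
#'
#' @param reports Assembled `cirvi_cases`.
#' @param deleted_caseids CASEIDs from FDA deletion lists (optional).
#' @param anti_infective_names Anti-infective name list (optional; defaults
#'   to the shipped starter list).
#' @param window_days Anti-infective look-back window (default 14).
#' @param require_complement Passed to [screen_validity()].
#' @return `list(kept, removed)`; `removed` has one row per excluded report
#'   with columns `primaryid`, `reason`.
#' @export
run_processing <- function(reports, deleted_caseids = character(0),
                           anti_infective_names = read_line_list(
                             system.file("extdata", "anti_infectives.tsv",
                                         package = "cirvi")),
                           window_days = 14L, require_complement = TRUE) {
  s1 <- dedupe_by_case(reports)
  s2 <- apply_deletion_list(s1$kept, deleted_caseids)
  s3 <- dedupe_by_content(s2$kept)
  s4 <- screen_validity(s3$kept, require_complement = require_complement)
  s5 <- exclude_prior_anti_infective(s4$kept, anti_infective_names, window_days)
  removed <- data.table::rbindlist(list(s1$removed, s2$removed, s3$removed,
                                        s4$removed, s5$removed))
  list(kept = s5$kept, removed = removed)
}
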