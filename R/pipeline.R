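# End-to-end orchestration: ingest -> process -> screen -> TTO -> risk
# models, with a run manifest and tidy TSV outputs.

#' Descriptive summary of a processed case set
#'
#' Demographics, reporter occupation, country, outcome shares and yearly
#' report counts. Shares over categorical fields are reported both as share
#' of all reports and share of reports with the field known. Outcome
#' classes partition the reports: fatal (DE present), non_fatal (outcomes
#' recorded without DE), missing (no outcome recorded).
#'
#' @param reports `cirvi_cases`.
#' @return List of data.tables: `overview`, `sex`, `reporter`, `country`,
#'   `outcome`, `yearly`, `age_weight`.
#' @export
descriptive_summary <- function(reports) {
  dt <- data.table::as.data.table(reports)
  n <- nrow(dt)
  share_table <- function(x, missing_label = "unknown") {
    tab <- data.table::as.data.table(table(value = x))
    data.table::setnames(tab, "N", "n")
    known <- sum(tab$n[tab$value != missing_label])
    tab[, share_of_all := n / sum(n) * 100]
    tab[, share_of_known := ifelse(value == missing_label, NA_real_,
                                   n / known * 100)]
    tab[]
  }
  outcome_class <- vapply(dt$outcomes, function(o) {
    if ("DE" %in% o) "fatal" else if (length(o) > 0) "non_fatal" else "missing"
  }, character(1))
  fatal_flag <- outcome_class == "fatal"
  age_weight <- data.table::data.table(
    group = c("overall", "fatal", "non_fatal"),
    n = c(n, sum(fatal_flag), sum(outcome_class == "non_fatal")),
    age_median = c(stats::median(dt$age_years, na.rm = TRUE),
                   stats::median(dt$age_years[fatal_flag], na.rm = TRUE),
                   stats::median(dt$age_years[outcome_class == "non_fatal"], na.rm = TRUE)),
    age_mean = c(mean(dt$age_years, na.rm = TRUE),
                 mean(dt$age_years[fatal_flag], na.rm = TRUE),
                 mean(dt$age_years[outcome_class == "non_fatal"], na.rm = TRUE)),
    weight_median = c(stats::median(dt$weight_kg, na.rm = TRUE),
                      stats::median(dt$weight_kg[fatal_flag], na.rm = TRUE),
                      stats::median(dt$weight_kg[outcome_class == "non_fatal"], na.rm = TRUE)),
    weight_mean = c(mean(dt$weight_kg, na.rm = TRUE),
                    mean(dt$weight_kg[fatal_flag], na.rm = TRUE),
                    mean(dt$weight_kg[outcome_class == "non_fatal"], na.rm = TRUE)))
  yearly <- dt[!is.na(fda_date),
               list(n = .N), by = list(year = data.table::year(fda_date))]
  data.table::setorder(yearly, year)
  list(
    overview = data.table::data.table(
      n_reports = n,
      n_fatal = sum(fatal_flag),
      pct_fatal = sum(fatal_flag) / n * 100,
      n_non_fatal = sum(outcome_class == "non_fatal"),
      pct_non_fatal = sum(outcome_class == "non_fatal") / n * 100,
      n_missing_outcome = sum(outcome_class == "missing")),
    sex = share_table(dt$sex),
    reporter = share_table(dt$reporter),
    country = share_table(dt$country, missing_label = ""),
    outcome = share_table(outcome_class, missing_label = "missing"),
    yearly = yearly[],
    age_weight = age_weight)
}

#' Assemble a pipeline run configuration
#'
#' Either `input_dir` (a directory holding DEMO.txt, DRUG.txt, ... in the
#' "$"-delimited dialect) or `simulate` (a `cirvi_config`) must be given.
#'
#' @param input_dir Directory of FAERS-format tables, or `NULL`.
#' @param simulate A `cirvi_config` to generate inputs, or `NULL`.
#' @param outdir Output directory.
#' @param seed Integer seed for all stochastic stages (mandatory).
#' @param draws Monte Carlo draws for the BCPNN (default 100000).
#' @param drug_map_path,meddra_path,deletion_list_path,anti_infective_path
#'   Resource paths; defaults are the shipped fixtures (no deletion list).
#' @param do_signals,do_tto,do_risk Stage toggles.
#' @return A validated `cirvi_run_config` list.
#' @export
run_config <- function(input_dir = NULL, simulate = NULL,
                       outdir = tempfile("cirvi_run_"), seed,
                       draws = 100000L,
                       drug_map_path = NULL, meddra_path = NULL,
                       deletion_list_path = NULL, anti_infective_path = NULL,
                       do_signals = TRUE, do_tto = TRUE, do_risk = TRUE) {
  if (is.null(input_dir) == is.null(simulate)) {
    stop("exactly one of input_dir or simulate must be given")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  for (p in c(input_dir, drug_map_path, meddra_path, deletion_list_path,
              anti_infective_path)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  structure(list(input_dir = input_dir, simulate = simulate, outdir = outdir,
                 seed = as.integer(seed), draws = as.integer(draws),
                 drug_map_path = drug_map_path, meddra_path = meddra_path,
                 deletion_list_path = deletion_list_path,
                 anti_infective_path = anti_infective_path,
                 do_signals = do_signals, do_tto = do_tto, do_risk = do_risk),
            class = "cirvi_run_config")
}

#' Run the full analysis pipeline
#'
#' Stages in fixed order: (1) simulate (optional), (2) ingest + assemble
#' (background retained), (3) processing protocol, (4) descriptive
#' summary, (5) eight-method PT screen with CIRVI classification, (6)
#' time-to-onset analysis of the viral PTs, (7) risk models. Outputs are
#' written as TSVs under `cfg$outdir` together with a plain-text run
#' manifest of stage row counts.
#'
#' @param cfg A `cirvi_run_config`.
#' @return List with the in-memory results of each stage plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cirvi_run_config"))
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  manifest <- c(sprintf("cirvi run, package version %s",
                        as.character(utils::packageVersion("cirvi"))),
                sprintf("seed: %d, draws: %d", cfg$seed, cfg$draws))
  note <- function(...) manifest <<- c(manifest, sprintf(...))

  input_dir <- cfg$input_dir
  if (!is.null(cfg$simulate)) {
    sim <- simulate_faers(cfg$simulate, file.path(cfg$outdir, "sim"))
    input_dir <- sim$dir
    note("simulated %d reports (+%d injected)",
         cfg$simulate$n_reports,
         nrow(sim$ledger) - cfg$simulate$n_reports)
  }
  tables <- list()
  for (nm in c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")) {
    path <- file.path(input_dir, paste0(nm, ".txt"))
    if (file.exists(path)) {
      tables[[nm]] <- read_faers_table(path, nm)
      note("input %s: %d rows, md5 %s", nm, nrow(tables[[nm]]),
           unname(tools::md5sum(path)))
    }
  }
  map <- if (is.null(cfg$drug_map_path)) load_drug_map() else load_drug_map(cfg$drug_map_path)
  meddra <- if (is.null(cfg$meddra_path)) load_meddra_map() else load_meddra_map(cfg$meddra_path)
  cases <- assemble_cases(tables, map, meddra, keep_unmatched = TRUE)
  note("assembled %d case reports", nrow(cases))

  deletion <- read_line_list(cfg$deletion_list_path)
  ai_names <- if (is.null(cfg$anti_infective_path)) {
    read_line_list(system.file("extdata", "anti_infectives.tsv", package = "cirvi"))
  } else read_line_list(cfg$anti_infective_path)
  pr <- run_processing(cases, deleted_caseids = deletion,
                       anti_infective_names = ai_names,
                       require_complement = FALSE)
  cases <- pr$kept
  for (reason in unique(pr$removed$reason)) {
    note("processing removed %d report(s): %s",
         sum(pr$removed$reason == reason), reason)
  }
  note("%d reports after processing (%d complement, %d background)",
       nrow(cases), sum(cases$drug_class != "other"),
       sum(cases$drug_class == "other"))
  data.table::fwrite(pr$removed, file.path(cfg$outdir, "exclusions.tsv"), sep = "\t")

  complement <- cases[cases$drug_class != "other", ]
  class(complement) <- class(cases)
  desc <- descriptive_summary(complement)
  data.table::fwrite(desc$overview, file.path(cfg$outdir, "descriptive_overview.tsv"), sep = "\t")
  data.table::fwrite(desc$yearly, file.path(cfg$outdir, "yearly_counts.tsv"), sep = "\t")

  screen <- tto <- risk <- NULL
  if (cfg$do_signals) {
    screen <- screen_pt_universe(cases, seed = cfg$seed, draws = cfg$draws)
    data.table::fwrite(screen$summary, file.path(cfg$outdir, "pt_screen.tsv"), sep = "\t")
    panels_tidy <- data.table::rbindlist(lapply(names(screen$panelsets), function(pt) {
      data.table::rbindlist(lapply(.strata, function(st) {
        tidy_panel(screen$panelsets[[pt]]$panels[[st]], pt = pt, stratum = st)
      }))
    }))
    data.table::fwrite(panels_tidy, file.path(cfg$outdir, "signal_panels.tsv"), sep = "\t")
    note("screened %d PT(s); %d classified CIRVI",
         nrow(screen$summary), sum(screen$summary$cirvi))
  }
  if (cfg$do_tto) {
    recs <- compute_tto(complement, cirvi_viral_pts())
    tto <- list(records = recs,
                by_outcome = summarize_tto(recs, "outcome_group"),
                by_class = summarize_tto(recs, "drug_class"))
    if (length(unique(recs$outcome_group)) > 1) {
      tto$test_outcome <- compare_tto_groups(recs, "outcome_group")
    }
    if (length(unique(recs$drug_class)) > 1) {
      tto$test_class <- compare_tto_groups(recs, "drug_class")
    }
    data.table::fwrite(tto$by_outcome$summary, file.path(cfg$outdir, "tto_summary.tsv"), sep = "\t")
    data.table::fwrite(tto$by_outcome$ecdf, file.path(cfg$outdir, "tto_ecdf.tsv"), sep = "\t")
    note("TTO records: %d (excluded: %d missing, %d negative)",
         nrow(recs), attr(recs, "n_excluded")$missing,
         attr(recs, "n_excluded")$negative)
  }
  if (cfg$do_risk) {
    frame <- build_analysis_frame(complement)
    uni <- list()
    for (pred in c("drug_class", "sex", "age_bin", "weight_bin", "quarter")) {
      fit <- try(univariate_logit(frame, "outcome_fatal", pred), silent = TRUE)
      if (!inherits(fit, "try-error")) uni[[pred]] <- fit
    }
    cirvi_fit <- try(univariate_logit(
      cbind(frame, cirvi_label = factor(ifelse(frame$outcome_cirvi == 1, "CIRVI", "other"),
                                        levels = c("other", "CIRVI"))),
      "outcome_fatal", "cirvi_label"), silent = TRUE)
    if (!inherits(cirvi_fit, "try-error")) uni[["cirvi"]] <- cirvi_fit
    forest <- data.table::rbindlist(lapply(names(uni), function(p)
      cbind(term = p, uni[[p]]$or_table)))
    data.table::fwrite(forest, file.path(cfg$outdir, "univariate_or.tsv"), sep = "\t")
    rcs_age <- try(fit_rcs_logit(frame, "outcome_fatal", "age_years",
                                 adjust = c("drug_class", "sex", "weight_kg")),
                   silent = TRUE)
    strat <- stratified_or(frame, "outcome_fatal", "outcome_cirvi", "sex")
    data.table::fwrite(strat, file.path(cfg$outdir, "stratified_or.tsv"), sep = "\t")
    risk <- list(univariate = uni,
                 rcs_age = if (!inherits(rcs_age, "try-error")) rcs_age,
                 stratified = strat)
    if (!is.null(risk$rcs_age)) {
      curve <- adjusted_curve(risk$rcs_age,
                              profile = list(weight_kg = 64.2))
      data.table::fwrite(curve$curve, file.path(cfg$outdir, "rcs_age_curve.tsv"), sep = "\t")
      risk$age_curve <- curve
      note("RCS(age): k=%d, p_nonlinear=%.3g, curve minimum at %.2f y",
           risk$rcs_age$k, risk$rcs_age$p_nonlinear, curve$minimizer)
    }
    note("risk models fitted on frame of %d complement reports", nrow(frame))
  }
  writeLines(manifest, file.path(cfg$outdir, "manifest.txt"))
  list(cases = cases, removed = pr$removed, descriptive = desc,
       screen = screen, tto = tto, risk = risk, manifest = manifest,
       outdir = cfg$outdir)
}
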