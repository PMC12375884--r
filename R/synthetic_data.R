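# Synthetic FAERS-format report generator with planted structure.
#
# The generator emulates the reporting universe the analysis assumes: a
# large non-complement background plus complement-inhibitor reports
# (C3/C5/FactorB), each report carrying demographics, a primary-suspect
# drug, MedDRA-style reaction PTs (including the four viral PTs with
# planted reporting-odds multipliers), outcome codes, therapy start and
# event dates with outcome-group-specific lognormal onset laws, a planted
# fatality logit, field-level missingness, and injected duplicate /
# prior-anti-infective reports. A ground-truth ledger records every latent
# assignment so each pipeline stage is checkable by parameter recovery.
#
# All randomness flows from one seeded base-R generator; draws happen in a
# fixed documented order (class, demographics, dates, viral PTs, other
# PTs, fatality, onset, masks, injections), so a given config + seed is
# byte-reproducible.

#' Default synthetic-cohort configuration
#'
#' Defaults encode the study conditions the package is tested against:
#' planted viral reporting-odds multipliers 2.62 (C5/FactorB) and 3.52
#' (C3); fatality logit with class effect 3.55 (C5 vs C3), female 0.77,
#' quarter effects, a U-shaped age term with vertex 30 y, an L-shaped
#' weight term, and a CIRVI-event coefficient of 0.22 on the odds scale;
#' onset-time lognormals with medians 12 d (fatal) and 187 d (non-fatal);
#' demographics with median age ~42 y, median weight ~64.2 kg and 45.25%
#' female. Viral baseline probabilities are expressed at the covariate
#' reference profile (male, <18 y, <45 kg, Q1).
#'
#' @param n_reports Total reports to generate (default 60000).
#' @param seed Integer seed.
#' @param ... Named overrides of any default element.
#' @return A `cirvi_config` list.
#' @export
synthetic_config <- function(n_reports = 60000L, seed = 1L, ...) {
  cfg <- list(
    n_reports = as.integer(n_reports),
    seed = as.integer(seed),
    background_share = 0.80,
    class_shares = c(C3 = 0.10, C5 = 0.82, FactorB = 0.08),
    viral_base = c("Influenza" = 0.055, "Herpes zoster" = 0.032,
                   "Gastroenteritis viral" = 0.018, "Viral infection" = 0.030),
    viral_multiplier_overall = 2.62,
    viral_multiplier_C3 = 3.52,
    # odds multipliers on viral reporting by covariate (reference profile:
    # male, age <18, weight <45, Q1)
    viral_cov = list(
      age_bin = c("<18" = 1, "18-64" = 0.90, "65-74" = 0.70, ">=75" = 0.43),
      sex = c(M = 1, F = 1.16, unknown = 1),
      weight_bin = c("<45" = 1, "45-80" = 0.57, ">=80" = 0.54),
      quarter = c(Q1 = 1, Q2 = 0.83, Q3 = 0.56, Q4 = 0.58)
    ),
    other_pts = c("Headache" = 0.15, "Fatigue" = 0.12, "Anaemia" = 0.12,
                  "Haemolysis" = 0.10, "Pyrexia" = 0.10, "Nausea" = 0.08,
                  "Drug ineffective" = 0.10, "Arthralgia" = 0.06,
                  "Dizziness" = 0.06, "Sepsis" = 0.03, "Pneumonia" = 0.04,
                  "Urinary tract infection" = 0.04),
    fatality_model = list(
      intercept = -3.5,
      class = c(C3 = 0, C5 = log(3.55), FactorB = log(1.8), other = 0),
      sex = c(M = 0, F = log(0.77), unknown = 0),
      quarter = c(Q1 = 0, Q2 = log(0.95), Q3 = log(0.88), Q4 = log(0.95)),
      age_vertex = 30, age_quad = 2.23e-4, age_lin = 0,
      weight_knee = 60, weight_slope = 0.03,   # per kg below the knee
      cirvi = log(0.22)
    ),
    tto_laws = list(fatal = list(median = 12, sdlog = 1),
                    non_fatal = list(median = 187, sdlog = 1)),
    demographics = list(
      age_mean = 42.5, age_sd = 19, age_range = c(1, 95),
      weight_median = 64.2, weight_sdlog = 0.25, weight_range = c(30, 200),
      sex = c(F = 0.4525, M = 0.50, unknown = 0.0475),
      reporter = stats::setNames(c(0.70, 0.15, 0.05, 0.07, 0.01, 0.02),
                                 c("CN", "MD", "PH", "OT", "LW", "")),
      country = c(US = 0.85, CA = 0.04, GB = 0.04, JP = 0.03, FR = 0.02,
                  DE = 0.02)
    ),
    date_range = as.Date(c("2008-01-01", "2024-06-30")),
    report_delay_days = c(7L, 180L),
    missingness = c(age = 0.15, weight = 0.25, event_dt = 0.25,
                    ther_start = 0.20),
    duplicate_injection_rate = 0.05,
    anti_infective_injection_rate = 0.02,
    background_drugs = c("rituximab", "adalimumab", "metformin",
                         "lisinopril", "ibuprofen", "atorvastatin"),
    anti_infectives = c("amoxicillin", "azithromycin", "aciclovir",
                        "oseltamivir", "fluconazole")
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- overrides[[nm]]
  }
  validate_config(structure(cfg, class = "cirvi_config"))
}

#' Validate a synthetic configuration
#' @param cfg A `cirvi_config`.
#' @return `cfg` invisibly; errors on infeasible settings.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$n_reports > 0, cfg$background_share >= 0,
            cfg$background_share <= 1,
            abs(sum(cfg$class_shares) - 1) < 1e-8,
            all(cfg$viral_base > 0), all(cfg$viral_base < 1),
            cfg$viral_multiplier_overall > 0, cfg$viral_multiplier_C3 > 0,
            all(cfg$missingness >= 0), all(cfg$missingness <= 1))
  # probability overflow check at the most extreme covariate profile
  worst_mult <- max(cfg$viral_multiplier_overall, cfg$viral_multiplier_C3) *
    max(cfg$viral_cov$age_bin) * max(cfg$viral_cov$sex) *
    max(cfg$viral_cov$weight_bin) * max(cfg$viral_cov$quarter)
  p_worst <- plant_viral_signal(max(cfg$viral_base), worst_mult)
  if (p_worst > 0.95) {
    stop("infeasible config: viral probability reaches ",
         signif(p_worst, 3), " after multipliers (saturation breaks the ",
         "odds-planting interpretation)")
  }
  invisible(cfg)
}

#' Multiply reporting odds of an event
#'
#' `odds(p_out) = multiplier * odds(p_base)`, the planting rule that makes
#' the large-sample ROR of exposed vs background equal the multiplier.
#'
#' @param base_p Baseline probability (vector).
#' @param multiplier Odds multiplier (> 0).
#' @return Adjusted probability vector.
#' @export
plant_viral_signal <- function(base_p, multiplier) {
  stopifnot(all(base_p >= 0), all(base_p < 1), all(multiplier > 0))
  stats::plogis(stats::qlogis(base_p) + log(multiplier))
}

#' Draw onset times from a configured outcome-group law
#'
#' Lognormal with the configured median and log-scale sd, rounded to whole
#' days.
#'
#' @param n Number of draws.
#' @param group `"fatal"` or `"non_fatal"`.
#' @param cfg A `cirvi_config`.
#' @return Integer vector of days.
#' @export
draw_tto_days <- function(n, group = c("fatal", "non_fatal"), cfg) {
  group <- match.arg(group)
  law <- cfg$tto_laws[[group]]
  as.integer(round(stats::rlnorm(n, meanlog = log(law$median),
                                 sdlog = law$sdlog)))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.age_bin_of <- function(age) {
  cut(age, breaks = c(-Inf, 18, 65, 75, Inf),
      labels = c("<18", "18-64", "65-74", ">=75"), right = FALSE)
}
.weight_bin_of <- function(w) {
  cut(w, breaks = c(-Inf, 45, 80, Inf),
      labels = c("<45", "45-80", ">=80"), right = FALSE)
}

#' Draw latent per-report structure for a configuration
#'
#' Internal engine behind [simulate_faers()]; exported because tests and
#' recovery experiments use the latent frame directly.
#'
#' @param cfg A `cirvi_config` (the seed is consumed here).
#' @return A `data.table` of latent truths, one row per report.
#' @export
draw_latents <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_reports
  dem <- cfg$demographics

  is_bg <- stats::runif(n) < cfg$background_share
  cls <- character(n)
  cls[is_bg] <- "other"
  cls[!is_bg] <- .sample_cat(sum(!is_bg), cfg$class_shares)

  age <- .rtruncnorm(n, dem$age_mean, dem$age_sd, dem$age_range[1], dem$age_range[2])
  weight <- pmin(pmax(stats::rlnorm(n, log(dem$weight_median), dem$weight_sdlog),
                      dem$weight_range[1]), dem$weight_range[2])
  sex <- .sample_cat(n, dem$sex)
  reporter <- .sample_cat(n, dem$reporter)
  country <- .sample_cat(n, dem$country)

  span <- as.integer(cfg$date_range[2] - cfg$date_range[1])
  therapy_start <- cfg$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  quarter <- paste0("Q", (data.table::month(therapy_start) - 1L) %/% 3L + 1L)

  age_bin <- as.character(.age_bin_of(age))
  weight_bin <- as.character(.weight_bin_of(weight))
  cov_mult <- cfg$viral_cov$age_bin[age_bin] * cfg$viral_cov$sex[sex] *
    cfg$viral_cov$weight_bin[weight_bin] * cfg$viral_cov$quarter[quarter]
  class_mult <- data.table::fifelse(
    cls == "other", 1,
    data.table::fifelse(cls == "C3", cfg$viral_multiplier_C3,
                        cfg$viral_multiplier_overall))

  viral <- matrix(FALSE, n, length(cfg$viral_base),
                  dimnames = list(NULL, names(cfg$viral_base)))
  for (j in seq_along(cfg$viral_base)) {
    p <- plant_viral_signal(cfg$viral_base[j], class_mult * cov_mult)
    viral[, j] <- stats::runif(n) < p
  }
  other <- matrix(FALSE, n, length(cfg$other_pts),
                  dimnames = list(NULL, names(cfg$other_pts)))
  for (j in seq_along(cfg$other_pts)) {
    other[, j] <- stats::runif(n) < cfg$other_pts[j]
  }
  # guarantee a non-empty reaction list without touching the viral draws
  none <- !(rowSums(viral) + rowSums(other) > 0)
  if (any(none)) {
    filler <- sample(names(cfg$other_pts), sum(none), replace = TRUE,
                     prob = cfg$other_pts)
    other[cbind(which(none), match(filler, colnames(other)))] <- TRUE
  }
  cirvi_true <- rowSums(viral) > 0

  fm <- cfg$fatality_model
  lp <- fm$intercept + fm$class[cls] + fm$sex[sex] + fm$quarter[quarter] +
    fm$age_quad * (age - fm$age_vertex)^2 + fm$age_lin * age +
    fm$weight_slope * pmax(fm$weight_knee - weight, 0) +
    fm$cirvi * cirvi_true
  fatal <- stats::runif(n) < stats::plogis(lp)

  tto <- integer(n)
  tto[fatal] <- draw_tto_days(sum(fatal), "fatal", cfg)
  tto[!fatal] <- draw_tto_days(sum(!fatal), "non_fatal", cfg)
  event_date <- therapy_start + tto
  delay <- sample(cfg$report_delay_days[1]:cfg$report_delay_days[2], n,
                  replace = TRUE)
  fda_date <- event_date + delay

  caseid <- as.character(20000000L + seq_len(n))
  dt <- data.table::data.table(
    idx = seq_len(n), caseid = caseid, primaryid = paste0(caseid, "1"),
    is_background = is_bg, drug_class = cls,
    age = age, weight = weight, sex = sex, reporter = reporter,
    country = country, therapy_start = therapy_start, quarter = quarter,
    cirvi_true = cirvi_true, fatal = fatal, tto_days = tto,
    event_date = event_date, fda_date = fda_date)
  dt[, (colnames(viral)) := data.table::as.data.table(viral)]
  dt[, (colnames(other)) := data.table::as.data.table(other)]
  mis <- cfg$missingness
  dt[, miss_age := stats::runif(n) < mis["age"]]
  dt[, miss_weight := stats::runif(n) < mis["weight"]]
  dt[, miss_event := stats::runif(n) < mis["event_dt"]]
  dt[, miss_ther := stats::runif(n) < mis["ther_start"]]
  dt[]
}

.drug_synonyms <- list(
  pegcetacoplan = c("pegcetacoplan", "EMPAVELI", "Aspaveli"),
  crovalimab = c("crovalimab", "PIASKY"),
  eculizumab = c("eculizumab", "SOLIRIS"),
  pozelimab = c("pozelimab", "VEOPOZ"),
  ravulizumab = c("ravulizumab", "ULTOMIRIS", "ravulizumab-cwvz"),
  iptacopan = c("iptacopan", "FABHALTA")
)
.class_drugs <- list(C3 = "pegcetacoplan",
                     C5 = c("crovalimab", "eculizumab", "pozelimab", "ravulizumab"),
                     FactorB = "iptacopan")

#' Generate a synthetic FAERS-format dataset on disk
#'
#' Writes DEMO, DRUG, REAC, OUTC, THER and INDI tables in the "$"-delimited
#' FAERS dialect plus a ground-truth ledger TSV and a config echo. Injected
#' duplicate reports (CASEID versions and content duplicates) and
#' prior-anti-infective reports are marked in the ledger.
#'
#' @param cfg A `cirvi_config`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with `dir`, file paths, and the `ledger`
#'   data.table.
#' @export
simulate_faers <- function(cfg, dir = tempfile("cirvi_sim_")) {
  lat <- draw_latents(cfg)
  n <- nrow(lat)
  viral_names <- names(cfg$viral_base)
  other_names <- names(cfg$other_pts)

  lat[, ps_drug := NA_character_]
  for (cl in names(.class_drugs)) {
    i <- which(lat$drug_class == cl)
    if (length(i)) lat[i, ps_drug := sample(.class_drugs[[cl]], length(i), replace = TRUE)]
  }
  i <- which(lat$drug_class == "other")
  if (length(i)) lat[i, ps_drug := sample(cfg$background_drugs, length(i), replace = TRUE)]
  # reported name: random synonym for complement drugs
  lat[, drugname := ps_drug]
  for (cl in setdiff(unique(lat$ps_drug), cfg$background_drugs)) {
    i <- which(lat$ps_drug == cl)
    syns <- .drug_synonyms[[cl]]
    if (!is.null(syns)) lat[i, drugname := sample(syns, length(i), replace = TRUE)]
  }

  # injections -----------------------------------------------------------
  lat[, injected := ""]
  lat[, anti_infective := FALSE]
  n_ai <- round(cfg$anti_infective_injection_rate * n)
  if (n_ai > 0) {
    ai_idx <- sample(which(!lat$miss_ther), n_ai)
    lat[ai_idx, anti_infective := TRUE]
    lat[ai_idx, ai_name := sample(cfg$anti_infectives, n_ai, replace = TRUE)]
    lat[ai_idx, ai_offset := sample(1:14, n_ai, replace = TRUE)]
  }

  n_dup <- round(cfg$duplicate_injection_rate * n)
  dup_rows <- NULL
  if (n_dup > 0) {
    complete_key <- !lat$miss_age & !lat$miss_event & lat$sex != "unknown"
    n_case <- n_dup %/% 2
    case_src <- sample(n, n_case)
    pool <- setdiff(which(complete_key), case_src)
    cont_src <- sample(pool, min(n_dup - n_case, length(pool)))
    mk_dup <- function(src, kind) {
      d <- lat[src]
      if (kind == "caseid_version") {
        d[, primaryid := paste0(caseid, "0")]          # lower version
        d[, fda_date := fda_date - 30L]                # older submission
      } else {
        d[, caseid := as.character(10000000L + src)]   # new case, lower id
        d[, primaryid := paste0(caseid, "1")]
        d[, fda_date := fda_date + 3L]
      }
      d[, injected := kind]
      d[, dup_of := lat$primaryid[src]]
      d
    }
    dup_rows <- data.table::rbindlist(list(
      mk_dup(case_src, "caseid_version"),
      mk_dup(cont_src, "content_duplicate")), fill = TRUE)
  }
  lat[, dup_of := NA_character_]
  all_rows <- data.table::rbindlist(list(lat, dup_rows), fill = TRUE)

  # table assembly --------------------------------------------------------
  fmt_d <- function(d) format(d, "%Y%m%d")
  demo <- data.table::data.table(
    PRIMARYID = all_rows$primaryid,
    CASEID = all_rows$caseid,
    FDA_DT = fmt_d(all_rows$fda_date),
    EVENT_DT = data.table::fifelse(all_rows$miss_event, "",
                                   fmt_d(all_rows$event_date)),
    AGE = data.table::fifelse(all_rows$miss_age, "",
                              as.character(round(all_rows$age))),
    AGE_COD = data.table::fifelse(all_rows$miss_age, "", "YR"),
    SEX = data.table::fifelse(all_rows$sex == "unknown", "", all_rows$sex),
    WT = data.table::fifelse(all_rows$miss_weight, "",
                             as.character(round(all_rows$weight, 1))),
    WT_COD = data.table::fifelse(all_rows$miss_weight, "", "KG"),
    OCCP_COD = all_rows$reporter,
    REPORTER_COUNTRY = all_rows$country)

  drug <- data.table::data.table(
    PRIMARYID = all_rows$primaryid, DRUG_SEQ = "1",
    DRUGNAME = all_rows$drugname, PROD_AI = all_rows$ps_drug,
    ROLE_COD = "PS")
  ai_rows <- all_rows[anti_infective == TRUE]
  if (nrow(ai_rows) > 0) {
    drug <- data.table::rbindlist(list(drug, data.table::data.table(
      PRIMARYID = ai_rows$primaryid, DRUG_SEQ = "2",
      DRUGNAME = toupper(ai_rows$ai_name), PROD_AI = ai_rows$ai_name,
      ROLE_COD = "C")))
  }

  pt_cols <- c(viral_names, other_names)
  pres <- as.matrix(all_rows[, pt_cols, with = FALSE])
  nz <- which(pres, arr.ind = TRUE)
  reac <- data.table::data.table(PRIMARYID = all_rows$primaryid[nz[, 1]],
                                 PT = pt_cols[nz[, 2]])
  data.table::setorder(reac, PRIMARYID, PT)

  set.seed(cfg$seed + 1L)  # outcome-code embellishment stream
  m <- nrow(all_rows)
  outc_list <- vector("list", m)
  extra <- stats::runif(m)
  outc <- data.table::rbindlist(list(
    data.table::data.table(PRIMARYID = all_rows$primaryid[all_rows$fatal],
                           OUTC_COD = "DE"),
    data.table::data.table(
      PRIMARYID = all_rows$primaryid[!all_rows$fatal & extra < 0.25],
      OUTC_COD = "HO"),
    data.table::data.table(
      PRIMARYID = all_rows$primaryid[!all_rows$fatal & extra >= 0.25 & extra < 0.70],
      OUTC_COD = "OT")))
  data.table::setorder(outc, PRIMARYID)

  ther <- data.table::data.table(
    PRIMARYID = all_rows$primaryid[!all_rows$miss_ther],
    DSG_DRUG_SEQ = "1",
    START_DT = fmt_d(all_rows$therapy_start[!all_rows$miss_ther]))
  if (nrow(ai_rows) > 0) {
    ai_keep <- ai_rows[!ai_rows$miss_ther]
    ther <- data.table::rbindlist(list(ther, data.table::data.table(
      PRIMARYID = ai_keep$primaryid, DSG_DRUG_SEQ = "2",
      START_DT = fmt_d(ai_keep$therapy_start - ai_keep$ai_offset))))
  }
  data.table::setorder(ther, PRIMARYID, DSG_DRUG_SEQ)

  indi <- data.table::data.table(
    PRIMARYID = all_rows$primaryid, INDI_DRUG_SEQ = "1",
    INDI_PT = data.table::fifelse(all_rows$drug_class == "other",
                                  "Hypertension",
                                  "Paroxysmal nocturnal haemoglobinuria"))

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (nm in c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")) {
    tab <- switch(nm, DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                  THER = ther, INDI = indi)
    paths[[nm]] <- file.path(dir, paste0(nm, ".txt"))
    write_faers_table(tab, paths[[nm]])
  }

  ledger <- all_rows[, list(primaryid, caseid, injected, dup_of,
                            is_background, drug_class, ps_drug,
                            age, weight, sex, quarter, country,
                            cirvi_true, fatal, tto_days,
                            therapy_start = fmt_d(therapy_start),
                            event_date = fmt_d(event_date),
                            anti_infective,
                            miss_age, miss_weight, miss_event, miss_ther)]
  ledger_path <- file.path(dir, "ledger.tsv")
  data.table::fwrite(ledger, ledger_path, sep = "\t")
  cfg_path <- file.path(dir, "config_echo.txt")
  writeLines(utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE)),
             cfg_path)
  invisible(list(dir = dir, paths = paths, ledger = ledger,
                 ledger_path = ledger_path, config_path = cfg_path))
}

#' Generate, re-ingest and assemble a synthetic cohort
#'
#' Convenience wrapper: [simulate_faers()] to a scratch directory, then
#' [read_faers_table()] + [assemble_cases()] on the written files (so the
#' file dialect is exercised), keeping background reports.
#'
#' @param cfg A `cirvi_config`.
#' @param process Also run [run_processing()] (background retained).
#'   Default `TRUE`.
#' @param dir Directory to write to (default: fresh tempdir, deleted on
#'   exit).
#' @return List: `cases` (assembled, optionally processed), `ledger`,
#'   `removed` (exclusion log when `process`).
#' @export
simulate_cases <- function(cfg, process = TRUE, dir = NULL) {
  cleanup <- is.null(dir)
  if (is.null(dir)) dir <- tempfile("cirvi_sim_")
  sim <- simulate_faers(cfg, dir)
  on.exit(if (cleanup) unlink(dir, recursive = TRUE))
  raw <- lapply(stats::setNames(nm = c("DEMO", "DRUG", "REAC", "OUTC",
                                       "THER", "INDI")),
                function(nm) read_faers_table(sim$paths[[nm]], nm))
  map <- load_drug_map()
  cases <- assemble_cases(raw, map, keep_unmatched = TRUE)
  removed <- NULL
  if (process) {
    pr <- run_processing(cases, require_complement = FALSE)
    cases <- pr$kept
    removed <- pr$removed
  }
  list(cases = cases, ledger = sim$ledger, removed = removed)
}
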