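# Shared fixtures, built in code.

# Write a minimal FAERS-format table set to `dir` and return the paths.
# `rows` is a list of per-report specs:
#   list(pid, caseid, fda, event = "", age = "", age_cod = "", sex = "",
#        wt = "", wt_cod = "", country = "US", occp = "CN",
#        drugs = data.frame(name, ai, role, seq),
#        pts = c(...), outc = c(...), ther = data.frame(seq, start),
#        indi = c(...))
write_fixture_tables <- function(rows, dir = tempfile("fixture_")) {
  dir.create(dir, showWarnings = FALSE)
  g <- function(r, f, d = "") if (is.null(r[[f]])) d else r[[f]]
  demo <- data.frame(
    PRIMARYID = vapply(rows, `[[`, "", "pid"),
    CASEID = vapply(rows, `[[`, "", "caseid"),
    FDA_DT = vapply(rows, `[[`, "", "fda"),
    EVENT_DT = vapply(rows, g, "", f = "event"),
    AGE = vapply(rows, g, "", f = "age"),
    AGE_COD = vapply(rows, g, "", f = "age_cod"),
    SEX = vapply(rows, g, "", f = "sex"),
    WT = vapply(rows, g, "", f = "wt"),
    WT_COD = vapply(rows, g, "", f = "wt_cod"),
    OCCP_COD = vapply(rows, g, "", f = "occp", d = "CN"),
    REPORTER_COUNTRY = vapply(rows, g, "", f = "country", d = "US"))
  drug <- do.call(rbind, lapply(rows, function(r) {
    d <- r$drugs
    data.frame(PRIMARYID = r$pid, DRUG_SEQ = as.character(d$seq),
               DRUGNAME = d$name, PROD_AI = d$ai, ROLE_COD = d$role)
  }))
  reac <- do.call(rbind, lapply(rows, function(r) {
    if (length(r$pts) == 0) return(NULL)
    data.frame(PRIMARYID = r$pid, PT = r$pts)
  }))
  outc <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$outc)) return(NULL)
    data.frame(PRIMARYID = r$pid, OUTC_COD = r$outc)
  }))
  ther <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$ther)) return(NULL)
    data.frame(PRIMARYID = r$pid, DSG_DRUG_SEQ = as.character(r$ther$seq),
               START_DT = r$ther$start)
  }))
  indi <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$indi)) return(NULL)
    data.frame(PRIMARYID = r$pid, INDI_DRUG_SEQ = "1", INDI_PT = r$indi)
  }))
  paths <- list()
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
               THER = ther, INDI = indi)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    paths[[nm]] <- file.path(dir, paste0(nm, ".txt"))
    write_faers_table(tabs[[nm]], paths[[nm]])
  }
  paths
}

read_fixture_tables <- function(paths) {
  out <- lapply(names(paths), function(nm) read_faers_table(paths[[nm]], nm))
  names(out) <- names(paths)
  out
}

# One standard report template with overridable fields.
fx_report <- function(pid, caseid = pid, fda = "20230115",
                      drugname = "SOLIRIS", ai = "eculizumab", role = "PS",
                      pts = "Influenza", ...) {
  out <- list(pid = pid, caseid = caseid, fda = fda,
              drugs = data.frame(name = drugname, ai = ai, role = role,
                                 seq = "1"),
              pts = pts)
  extras <- list(...)
  out[names(extras)] <- extras
  out
}

assemble_fixture <- function(rows, keep_unmatched = FALSE) {
  paths <- write_fixture_tables(rows)
  assemble_cases(read_fixture_tables(paths), load_drug_map(),
                 keep_unmatched = keep_unmatched)
}

# Cached mid-size synthetic cohort shared across test files.
.cohort_cache <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.cohort_cache$sim)) {
    cfg <- synthetic_config(n_reports = 30000L, seed = 424242L)
    .cohort_cache$sim <- simulate_cases(cfg)
    .cohort_cache$cfg <- cfg
  }
  .cohort_cache
}

# Random 2x2 tables for formula-oracle suites.
random_tables <- function(n, seed, max_cell = 400L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      cells <- c(sample(0:20, 1), sample(0:max_cell, 3, replace = TRUE))
      if (sum(cells) > 0) break
    }
    contingency(cells[1], cells[2], cells[3], cells[4])
  })
}
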