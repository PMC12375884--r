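# Reading and normalizing FAERS-format quarterly ASCII tables.
#
# FAERS public files are "$"-delimited text with one header line. Six tables
# make up a quarter: DEMO (one row per report version), DRUG, REAC, OUTC,
# THER, INDI (one row per drug/reaction/outcome/therapy-episode/indication).
# Rows are keyed by PRIMARYID; DEMO additionally carries CASEID and FDA_DT.

#' Required columns per FAERS table kind
#'
#' @format Named list mapping table name to its mandatory column names.
#' @keywords internal
.faers_required_cols <- list(
  DEMO = c("PRIMARYID", "CASEID", "FDA_DT"),
  DRUG = c("PRIMARYID", "DRUGNAME", "ROLE_COD"),
  REAC = c("PRIMARYID", "PT"),
  OUTC = c("PRIMARYID", "OUTC_COD"),
  THER = c("PRIMARYID", "START_DT"),
  INDI = c("PRIMARYID", "INDI_PT")
)

#' Read one FAERS-format quarterly table
#'
#' Parses a "$"-delimited FAERS ASCII file. All fields are kept verbatim as
#' character strings; no type coercion happens at this stage.
#'
#' @param path Path to the "$"-delimited text file.
#' @param table_name One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"THER"`, `"INDI"`.
#' @param source_quarter Optional quarter label (`"YYYYqQ"`), recorded as an
#'   attribute.
#' @return A `data.table` of character columns with attributes
#'   `table_name` and `source_quarter`. Row count equals the number of data
#'   lines in the file.
#' @export
read_faers_table <- function(path, table_name, source_quarter = NA_character_) {
  table_name <- match.arg(toupper(table_name), names(.faers_required_cols))
  if (!file.exists(path)) {
    stop("cannot read FAERS table: file not found: ", path)
  }
  dt <- data.table::fread(path, sep = "$", quote = "", colClasses = "character",
                          header = TRUE, na.strings = NULL, fill = TRUE)
  missing_cols <- setdiff(.faers_required_cols[[table_name]], names(dt))
  if (length(missing_cols) > 0) {
    stop(sprintf("FAERS %s file %s lacks required column(s): %s",
                 table_name, path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(dt) > 0 && any(!nzchar(dt$PRIMARYID))) {
    stop("FAERS ", table_name, " file contains rows with empty PRIMARYID")
  }
  data.table::setattr(dt, "table_name", table_name)
  data.table::setattr(dt, "source_quarter", source_quarter)
  dt[]
}

#' Write a FAERS-format table
#'
#' Inverse of [read_faers_table()]: writes a "$"-delimited file with a header
#' line. Values are written verbatim (no quoting), so fields must not contain
#' the delimiter.
#'
#' @param x A data.frame/data.table of character columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "$",
                     quote = FALSE, na = "")
  invisible(path)
}

#' Convert a FAERS AGE/AGE_COD pair to years
#'
#' Unit codes: `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY`
#' days, `HR` hours. Unparsable values, unknown codes and results outside
#' \[0, 120\] years all yield `NA` (defensive; never an error).
#'
#' @param age_value Character (or numeric) age value.
#' @param age_code Character unit code; empty or `NA` treated as years.
#' @return Numeric age in years, or `NA_real_`.
#' @export
normalize_age <- function(age_value, age_code) {
  n <- max(length(age_value), length(age_code))
  age_value <- rep_len(as.character(age_value), n)
  age_code <- rep_len(toupper(trimws(ifelse(is.na(age_code), "", as.character(age_code)))), n)
  v <- suppressWarnings(as.numeric(age_value))
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / 8766)
  mult <- ifelse(age_code == "", 1, unname(factor_map[age_code]))
  out <- v * mult
  out[is.na(out) | out < 0 | out > 120] <- NA_real_
  out
}

#' Convert a FAERS WT/WT_COD pair to kilograms
#'
#' Unit codes: `KG`, `LBS`, `GMS`. Unparsable values or results outside
#' (0, 400) kg yield `NA`.
#'
#' @param wt_value Character (or numeric) weight value.
#' @param wt_code Character unit code; empty or `NA` treated as kg.
#' @return Numeric weight in kg, or `NA_real_`.
#' @export
normalize_weight <- function(wt_value, wt_code) {
  n <- max(length(wt_value), length(wt_code))
  wt_value <- rep_len(as.character(wt_value), n)
  wt_code <- rep_len(toupper(trimws(ifelse(is.na(wt_code), "", as.character(wt_code)))), n)
  v <- suppressWarnings(as.numeric(wt_value))
  factor_map <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)
  mult <- ifelse(wt_code == "", 1, unname(factor_map[wt_code]))
  out <- v * mult
  out[is.na(out) | out <= 0 | out >= 400] <- NA_real_
  out
}

#' Parse a (possibly partial) FAERS date
#'
#' FAERS date fields are `YYYYMMDD`, `YYYYMM` or `YYYY`. A month-resolution
#' date is imputed to day 01; a year-only date carries no usable
#' sub-quarter information and is treated as missing.
#'
#' @param x Character vector of raw date fields.
#' @return A `Date` vector (`NA` where unusable).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(ifelse(is.na(x), "", as.character(x)))
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  ym <- grepl("^\\d{6}$", x)
  out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  out
}

.norm_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Load a drug synonym/class table
#'
#' Three-column TSV: `synonym`, `canonical`, `class` with class one of
#' `C3`, `C5`, `FactorB`. Synonyms must be unique after case-folding and
#' whitespace collapsing.
#'
#' @param path TSV path; defaults to the curated table shipped with the
#'   package (brand and generic names of the six approved complement
#'   inhibitors).
#' @return A `data.table` with columns `synonym` (normalized), `canonical`,
#'   `class`.
#' @export
load_drug_map <- function(path = system.file("extdata", "drug_class_map.tsv",
                                             package = "cirvi")) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  data.table::setnames(dt, tolower(names(dt)))
  stopifnot(all(c("synonym", "canonical", "class") %in% names(dt)))
  dt[, synonym := .norm_name(synonym)]
  if (anyDuplicated(dt$synonym)) {
    stop("drug map contains duplicate synonyms after normalization")
  }
  bad <- setdiff(unique(dt$class), c("C3", "C5", "FactorB"))
  if (length(bad) > 0) stop("unknown drug class in map: ", paste(bad, collapse = ", "))
  dt[]
}

#' Load a MedDRA-style PT hierarchy table
#'
#' Five-column TSV: `pt`, `hlt`, `hlgt`, `soc`, `primary_flag` (`Y`/`N`).
#' Each PT must carry the primary-SOC flag on exactly one row. The shipped
#' file is a small synthetic mapping covering the PTs used in examples and
#' tests; a licensed MedDRA export in the same format can be substituted.
#'
#' @param path TSV path; defaults to the shipped synthetic mapping.
#' @return A `data.table` with the five columns.
#' @export
load_meddra_map <- function(path = system.file("extdata",
                                               "meddra_map_synthetic.tsv",
                                               package = "cirvi")) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  data.table::setnames(dt, tolower(names(dt)))
  stopifnot(all(c("pt", "hlt", "hlgt", "soc", "primary_flag") %in% names(dt)))
  n_primary <- dt[, sum(primary_flag == "Y"), by = pt]
  if (any(n_primary$V1 != 1)) {
    stop("each PT must have exactly one primary-SOC row; offending PT(s): ",
         paste(n_primary[V1 != 1]$pt, collapse = ", "))
  }
  dt[]
}

#' Match a verbatim drug name against the class map
#'
#' Case-insensitive exact match after trimming and collapsing internal
#' whitespace; no fuzzy matching.
#'
#' @param verbatim_name Character vector of names as reported.
#' @param map A drug map from [load_drug_map()].
#' @return A `data.table` with columns `canonical` and `class`
#'   (`NA` where unmatched), one row per input name.
#' @export
match_drug <- function(verbatim_name, map) {
  key <- .norm_name(verbatim_name)
  idx <- match(key, map$synonym)
  data.table::data.table(canonical = map$canonical[idx], class = map$class[idx])
}

.occp_map <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
               OT = "other-health-professional", LW = "lawyer")

#' Assemble case reports from raw FAERS tables
#'
#' Joins DEMO/DRUG/REAC (required) and OUTC/THER/INDI (optional) into one
#' row per PRIMARYID. The primary-suspect (PS) drug is matched against the
#' drug class map on both DRUGNAME and PROD_AI (union semantics); by
#' default, reports whose PS drug is not a complement inhibitor are dropped.
#'
#' @param raw_tables Named list of tables from [read_faers_table()]; names
#'   `DEMO`, `DRUG`, `REAC` required, `OUTC`, `THER`, `INDI` optional.
#' @param map Drug class map ([load_drug_map()]).
#' @param meddra MedDRA-style map ([load_meddra_map()]); currently carried
#'   along for downstream SOC lookups, not used for filtering.
#' @param keep_unmatched If `TRUE`, reports whose PS drug is not in the map
#'   are retained with `drug_class = "other"` (needed as the reporting
#'   background for disproportionality denominators). Default `FALSE`.
#' @return A `data.table` of class `cirvi_cases`, one row per retained
#'   PRIMARYID, with list columns `reaction_pts`, `indications`, `outcomes`
#'   and `concomitant` (a per-report data.frame of name/start_date/role).
#' @export
assemble_cases <- function(raw_tables, map, meddra = NULL,
                           keep_unmatched = FALSE) {
  for (nm in c("DEMO", "DRUG", "REAC")) {
    if (is.null(raw_tables[[nm]])) stop("assemble_cases requires table ", nm)
  }
  demo <- data.table::as.data.table(raw_tables$DEMO)
  drug <- data.table::as.data.table(raw_tables$DRUG)
  reac <- data.table::as.data.table(raw_tables$REAC)

  get_col <- function(dt, col) if (col %in% names(dt)) dt[[col]] else rep("", nrow(dt))

  known <- unique(demo$PRIMARYID)
  orphan <- setdiff(unique(c(drug$PRIMARYID, reac$PRIMARYID)), known)
  if (length(orphan) > 0) {
    message(length(orphan), " PRIMARYID(s) in DRUG/REAC absent from DEMO; skipped")
  }

  # PS drug per report: match both DRUGNAME and PROD_AI, first hit wins
  drug <- drug[PRIMARYID %in% known]
  ps <- drug[toupper(trimws(ROLE_COD)) == "PS"]
  m_name <- match_drug(ps$DRUGNAME, map)
  m_ai <- match_drug(get_col(ps, "PROD_AI"), map)
  ps[, canonical := data.table::fifelse(!is.na(m_name$canonical),
                                        m_name$canonical, m_ai$canonical)]
  ps[, class := data.table::fifelse(!is.na(m_name$canonical),
                                    m_name$class, m_ai$class)]
  if (!"DRUG_SEQ" %in% names(ps)) ps[, DRUG_SEQ := NA_character_]
  pm <- ps[!is.na(class)]
  ambiguous <- pm[, list(nc = data.table::uniqueN(class)), by = PRIMARYID][nc > 1]
  if (nrow(ambiguous) > 0) {
    warning(nrow(ambiguous), " report(s) have PS drugs of more than one ",
            "complement class; excluded", call. = FALSE)
  }
  first_match <- pm[!duplicated(PRIMARYID)]
  unmatched <- ps[!PRIMARYID %in% pm$PRIMARYID][!duplicated(PRIMARYID)]
  ps_by_report <- data.table::rbindlist(list(
    data.table::data.table(PRIMARYID = first_match$PRIMARYID,
                           ps_drug = first_match$canonical,
                           drug_class = first_match$class,
                           ps_seq = first_match$DRUG_SEQ),
    data.table::data.table(PRIMARYID = unmatched$PRIMARYID,
                           ps_drug = .norm_name(unmatched$DRUGNAME),
                           drug_class = "other",
                           ps_seq = unmatched$DRUG_SEQ)))
  ps_by_report[PRIMARYID %in% ambiguous$PRIMARYID,
               `:=`(ps_drug = NA_character_, drug_class = NA_character_)]

  cases <- data.table::data.table(
    primaryid = demo$PRIMARYID,
    caseid = get_col(demo, "CASEID"),
    fda_date = parse_faers_date(get_col(demo, "FDA_DT")),
    event_date = parse_faers_date(get_col(demo, "EVENT_DT")),
    age_years = normalize_age(get_col(demo, "AGE"), get_col(demo, "AGE_COD")),
    sex = {
      s <- toupper(trimws(get_col(demo, "SEX")))
      data.table::fifelse(s %in% c("F", "M"), s, "unknown")
    },
    weight_kg = normalize_weight(get_col(demo, "WT"), get_col(demo, "WT_COD")),
    country = toupper(trimws(get_col(demo, "REPORTER_COUNTRY"))),
    reporter = {
      oc <- toupper(trimws(get_col(demo, "OCCP_COD")))
      r <- unname(.occp_map[oc])
      data.table::fifelse(is.na(r), "unknown", r)
    }
  )
  cases <- merge(cases, ps_by_report, by.x = "primaryid", by.y = "PRIMARYID",
                 all.x = TRUE, sort = FALSE)
  # drop: no PS row at all, or ambiguous multi-class PS
  cases <- cases[!is.na(drug_class)]
  if (!keep_unmatched) cases <- cases[drug_class != "other"]

  # list columns built by factor split (sorted and de-duplicated globally)
  split_to_col <- function(values, ids) {
    keep <- nzchar(values) & !is.na(values)
    dtl <- data.table::data.table(id = ids[keep], v = values[keep])
    dtl <- unique(dtl)
    data.table::setorder(dtl, id, v)
    sp <- split(dtl$v, factor(dtl$id, levels = unique(dtl$id)))
    out <- rep(list(character(0)), nrow(cases))
    idx <- match(names(sp), cases$primaryid)
    out[idx[!is.na(idx)]] <- sp[!is.na(idx)]
    out
  }
  cases[, reaction_pts := split_to_col(trimws(reac$PT), reac$PRIMARYID)]
  if (!is.null(raw_tables$OUTC)) {
    outc <- data.table::as.data.table(raw_tables$OUTC)
    cases[, outcomes := split_to_col(toupper(trimws(outc$OUTC_COD)), outc$PRIMARYID)]
  } else {
    cases[, outcomes := rep(list(character(0)), nrow(cases))]
  }
  if (!is.null(raw_tables$INDI)) {
    indi <- data.table::as.data.table(raw_tables$INDI)
    cases[, indications := split_to_col(trimws(indi$INDI_PT), indi$PRIMARYID)]
  } else {
    cases[, indications := rep(list(character(0)), nrow(cases))]
  }

  # therapy start of the PS drug (linked through DSG_DRUG_SEQ when present)
  cases[, therapy_start := as.Date(NA)]
  if (!is.null(raw_tables$THER)) {
    ther <- data.table::as.data.table(raw_tables$THER)
    ther[, start := parse_faers_date(START_DT)]
    if ("DSG_DRUG_SEQ" %in% names(ther) && "ps_seq" %in% names(cases)) {
      key <- paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ)
      idx <- match(paste(cases$primaryid, cases$ps_seq), key)
      cases[, therapy_start := ther$start[idx]]
    }
    # fall back to the earliest therapy date of the report
    first <- ther[!is.na(start), list(start = min(start)), by = PRIMARYID]
    fallback <- first$start[match(cases$primaryid, first$PRIMARYID)]
    need <- is.na(cases$therapy_start) & !is.na(fallback)
    if (any(need)) cases[need, therapy_start := fallback[need]]
  }

  # concomitant (non-PS) drugs with start dates where available
  nonps <- drug[toupper(trimws(ROLE_COD)) != "PS"]
  if (nrow(nonps) > 0 && !is.null(raw_tables$THER) &&
      "DRUG_SEQ" %in% names(nonps)) {
    ther <- data.table::as.data.table(raw_tables$THER)
    ther[, start := parse_faers_date(START_DT)]
    if ("DSG_DRUG_SEQ" %in% names(ther)) {
      nonps[, start_date := ther$start[match(paste(PRIMARYID, DRUG_SEQ),
                                             paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ))]]
    } else nonps[, start_date := as.Date(NA)]
  } else if (nrow(nonps) > 0) {
    nonps[, start_date := as.Date(NA)]
  }
  if (nrow(nonps) > 0) {
    con <- nonps[, list(con = list(data.frame(
      name = .norm_name(DRUGNAME),
      start_date = start_date,
      role = toupper(trimws(ROLE_COD)),
      stringsAsFactors = FALSE))), by = PRIMARYID]
    cases[, concomitant := con$con[match(primaryid, con$PRIMARYID)]]
  } else {
    cases[, concomitant := list(list(NULL))]
  }
  cases[, ps_seq := NULL]
  data.table::setorder(cases, primaryid)
  class(cases) <- c("cirvi_cases", class(cases))
  cases[]
}

#' @export
print.cirvi_cases <- function(x, ...) {
  cat("<cirvi_cases> ", nrow(x), " case report(s); classes: ",
      paste(sprintf("%s=%d", names(table(x$drug_class)), table(x$drug_class)),
            collapse = ", "), "\n", sep = "")
  NextMethod()
}
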