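test_that("read_faers_table preserves rows and enforces required columns", {
  dir <- tempfile()
  dir.create(dir)
  demo_path <- file.path(dir, "DEMO.txt")
  writeLines(c("PRIMARYID$CASEID$FDA_DT$SEX",
               "1001$100$20230101$F",
               "1002$101$20230102$M"), demo_path)
  dt <- read_faers_table(demo_path, "DEMO")
  expect_equal(nrow(dt), 2)
  expect_identical(dt$SEX, c("F", "M"))

  bad_path <- file.path(dir, "DRUG.txt")
  writeLines(c("PRIMARYID$DRUGNAME", "1001$SOLIRIS"), bad_path)
  expect_error(read_faers_table(bad_path, "DRUG"), "ROLE_COD")
  expect_error(read_faers_table(file.path(dir, "nope.txt"), "DEMO"),
               "not found")
})

test_that("write/read round-trip reproduces random fixture fields verbatim", {
  set.seed(99)
  rand_str <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c(LETTERS, letters, 0:9, " ", "-", "."),
                 sample(3:12, 1), replace = TRUE), collapse = ""), "")
  tab <- data.frame(PRIMARYID = as.character(1000 + 1:100),
                    CASEID = as.character(1:100),
                    FDA_DT = rep("20230101", 100),
                    FREETEXT = trimws(rand_str(100)),
                    MORE = trimws(rand_str(100)))
  p1 <- tempfile(); p2 <- tempfile()
  write_faers_table(tab, p1)
  back <- read_faers_table(p1, "DEMO")
  write_faers_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(back$FREETEXT, tab$FREETEXT)
})

test_that("age and weight unit conversions match hand-computed constants", {
  expect_equal(normalize_age("4", "DEC"), 40)
  expect_equal(normalize_age("6", "MON"), 0.5)
  expect_equal(normalize_age("14", "WK"), 14 * 7 / 365.25, tolerance = 1e-6)
  expect_equal(normalize_age("100", "DY"), 100 / 365.25, tolerance = 1e-6)
  expect_true(is.na(normalize_age("150", "YR")))
  expect_true(is.na(normalize_age("abc", "YR")))
  expect_true(is.na(normalize_age("-5", "YR")))

  expect_equal(normalize_weight("100", "LBS"), 45.3592, tolerance = 1e-6)
  expect_equal(normalize_weight("64200", "GMS"), 64.2, tolerance = 1e-6)
  expect_true(is.na(normalize_weight("0", "KG")))
  expect_true(is.na(normalize_weight("450", "KG")))
})

test_that("partial dates impute month starts and drop year-only values", {
  d <- parse_faers_date(c("20230415", "202304", "2023", "", "garbage"))
  expect_equal(d[1], as.Date("2023-04-15"))
  expect_equal(d[2], as.Date("2023-04-01"))
  expect_true(all(is.na(d[3:5])))
})

test_that("drug matching is exact, case- and whitespace-insensitive", {
  map <- load_drug_map()
  m <- match_drug(c("SOLIRIS", "  Eculizumab ", "ULTOMIRIS", "aspirin",
                    "iptacopan   hydrochloride"), map)
  expect_identical(m$canonical,
                   c("eculizumab", "eculizumab", "ravulizumab", NA,
                     "iptacopan"))
  expect_identical(m$class, c("C5", "C5", "C5", NA, "FactorB"))
})

test_that("assemble_cases keeps only primary-suspect complement reports", {
  rows <- list(
    fx_report("1011", pts = c("Influenza", "Headache")),
    fx_report("1021", drugname = "EMPAVELI", ai = "pegcetacoplan"),
    fx_report("1031", drugname = "FABHALTA", ai = "iptacopan"),
    fx_report("1041", drugname = "aspirin", ai = "aspirin"),
    # eculizumab present but only as concomitant -> dropped
    list(pid = "1051", caseid = "1051", fda = "20230101",
         drugs = data.frame(name = c("ibuprofen", "SOLIRIS"),
                            ai = c("ibuprofen", "eculizumab"),
                            role = c("PS", "C"), seq = c("1", "2")),
         pts = "Nausea"))
  cases <- assemble_fixture(rows)
  expect_equal(sort(cases$primaryid), c("1011", "1021", "1031"))
  expect_equal(cases$drug_class[cases$primaryid == "1011"], "C5")
  expect_setequal(cases$reaction_pts[cases$primaryid == "1011"][[1]],
                  c("Influenza", "Headache"))
  # background retained when asked
  all_cases <- assemble_fixture(rows, keep_unmatched = TRUE)
  expect_equal(nrow(all_cases), 5)
  expect_equal(sum(all_cases$drug_class == "other"), 2)
})

test_that("assembly fills outcomes, therapy start and demographics", {
  rows <- list(fx_report("2011", fda = "20230601", event = "20230520",
                         age = "4", age_cod = "DEC", sex = "F",
                         wt = "100", wt_cod = "LBS", occp = "MD",
                         outc = c("DE", "HO"),
                         ther = data.frame(seq = "1", start = "20230101"),
                         indi = "Paroxysmal nocturnal haemoglobinuria"))
  cases <- assemble_fixture(rows)
  expect_equal(cases$age_years, 40)
  expect_equal(cases$weight_kg, 45.3592, tolerance = 1e-6)
  expect_equal(cases$sex, "F")
  expect_equal(cases$reporter, "physician")
  expect_setequal(cases$outcomes[[1]], c("DE", "HO"))
  expect_equal(cases$therapy_start, as.Date("2023-01-01"))
  expect_equal(cases$event_date, as.Date("2023-05-20"))
})

test_that("assembly is order-independent", {
  rows <- list(fx_report("3011", pts = c("Influenza", "Nausea")),
               fx_report("3021", drugname = "ULTOMIRIS", ai = "ravulizumab",
                         pts = "Headache"),
               fx_report("3031", drugname = "EMPAVELI", ai = "pegcetacoplan"))
  paths1 <- write_fixture_tables(rows)
  paths2 <- write_fixture_tables(rev(rows))
  c1 <- assemble_cases(read_fixture_tables(paths1), load_drug_map())
  c2 <- assemble_cases(read_fixture_tables(paths2), load_drug_map())
  data.table::setkey(c1, primaryid); data.table::setkey(c2, primaryid)
  expect_equal(c1$primaryid, c2$primaryid)
  expect_equal(c1$reaction_pts, c2$reaction_pts)
  expect_equal(c1$drug_class, c2$drug_class)
})

test_that("meddra map loader enforces one primary SOC per PT", {
  md <- load_meddra_map()
  expect_true(all(table(md$pt[md$primary_flag == "Y"]) == 1))
  bad <- tempfile()
  writeLines(c("pt\thlt\thlgt\tsoc\tprimary_flag",
               "Influenza\ta\tb\tInfections and infestations\tY",
               "Influenza\ta\tb\tRespiratory disorders\tY"), bad)
  expect_error(load_meddra_map(bad), "exactly one primary")
})
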