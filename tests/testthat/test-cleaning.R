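test_that("deduplication keeps the latest FDA_DT, then the largest id", {
  demo <- parse_faers_records(
    raw_demo(primaryid = c(1000, 1001), caseid = c(100, 100),
             fda_dt = c("20230101", "20230301")), "DEMO")
  expect_equal(deduplicate_demo(demo)$primaryid, "1001")

  demo <- parse_faers_records(
    raw_demo(primaryid = c(1001, 1002), caseid = c(100, 100),
             fda_dt = c("20230301", "20230301")), "DEMO")
  expect_equal(deduplicate_demo(demo)$primaryid, "1002")

  empty <- parse_faers_records(raw_demo(character(0), character(0)), "DEMO")
  expect_equal(nrow(deduplicate_demo(empty)), 0)
})

test_that("numeric id comparison beats string order; non-numeric ids fall
           back to padded strings", {
  demo <- parse_faers_records(
    raw_demo(primaryid = c("900", "1002"), caseid = c("7", "7"),
             fda_dt = c("20230301", "20230301")), "DEMO")
  expect_equal(deduplicate_demo(demo)$primaryid, "1002")

  demo2 <- parse_faers_records(
    raw_demo(primaryid = c("A900", "A1002"), caseid = c("7", "7"),
             fda_dt = c("20230301", "20230301")), "DEMO")
  expect_message(kept <- deduplicate_demo(demo2), "non-numeric")
  expect_equal(kept$primaryid, "A1002")
})

test_that("deduplication is idempotent and matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    demo <- random_demo_fixture(n = sample(5:30, 1))
    once <- deduplicate_demo(demo)
    expect_equal(deduplicate_demo(once), once)
    expect_equal(sort(once$primaryid), oracle_dedup(demo))
    expect_equal(anyDuplicated(once$caseid), 0L)
  }
})

test_that("deleted-case removal drops exactly the listed caseids", {
  demo <- parse_faers_records(
    raw_demo(primaryid = 1:3, caseid = c("10", "20", "30")), "DEMO")
  expect_equal(remove_deleted(demo, "20")$caseid, c("10", "30"))
  expect_equal(remove_deleted(demo, character(0)), demo)
  expect_equal(nrow(remove_deleted(demo, c("10", "20", "30"))), 0)
})

test_that("remove_deleted and deduplicate commute when deletion is by case", {
  set.seed(202)
  for (i in 1:50) {
    demo <- random_demo_fixture(n = 20)
    del <- as.character(sample(1:8, 3))
    x <- remove_deleted(deduplicate_demo(demo), del)
    y <- deduplicate_demo(remove_deleted(demo, del))
    expect_equal(x[order(x$primaryid), ], y[order(y$primaryid), ],
                 ignore_attr = TRUE)
  }
})

test_that("chronology filter drops start-after-event and missing FDA_DT
           reports, with partition into kept and dropped", {
  demo <- raw_demo(primaryid = 1:4, caseid = 1:4,
                   fda_dt = c("20230110", "20230110", "20230110", ""),
                   event_dt = c("20230103", "20230103", "20230103",
                                "20230103"))
  drug <- raw_drug(primaryid = 1:4, drugname = "X",
                   start_dt = c("20230105", "20230101", "202301",
                                "20230101"))
  reports <- assemble_reports(parse_faers_records(demo, "DEMO"),
                              parse_faers_records(drug, "DRUG"),
                              parse_faers_records(raw_reac(1:4, "PT1"),
                                                  "REAC"))
  res <- chronology_filter(reports)
  expect_equal(nrow(res$kept$demo) + nrow(res$dropped), 4)
  expect_equal(res$dropped$primaryid, c("1", "4"))
  expect_equal(res$dropped$reason, c("chronology", "missing_fda_dt"))
  # month-precision start (report 3) is not evaluable and is kept
  expect_true("3" %in% res$kept$demo$primaryid)
  # start on/before event (report 2) is kept
  expect_true("2" %in% res$kept$demo$primaryid)
})

test_that("cohort membership needs a lexicon match with the PS role", {
  demo <- raw_demo(primaryid = 1:3, caseid = 1:3)
  drug <- raw_drug(primaryid = c(1, 2, 3), drugname = c("X", "X", "Y"),
                   role = c("PS", "C", "PS"))
  reports <- assemble_reports(parse_faers_records(demo, "DEMO"),
                              parse_faers_records(drug, "DRUG"),
                              parse_faers_records(raw_reac(1:3, "PT1"),
                                                  "REAC"))
  cohort <- build_cohort(reports, drug_lexicon("X", "X"))
  expect_equal(cohort$report_ids, "1")
})

test_that("strict single-suspect mode excludes reports with foreign
           suspect drugs", {
  demo <- raw_demo(primaryid = 1:2, caseid = 1:2)
  drug <- rbind(raw_drug(1, "X", role = "PS"),
                raw_drug(1, "Z", role = "SS", seq = "2"),
                raw_drug(2, "X", role = "PS"))
  reports <- assemble_reports(parse_faers_records(demo, "DEMO"),
                              parse_faers_records(drug, "DRUG"),
                              parse_faers_records(raw_reac(1:2, "PT1"),
                                                  "REAC"))
  lex <- drug_lexicon("X", "X")
  expect_setequal(build_cohort(reports, lex)$report_ids, c("1", "2"))
  expect_equal(build_cohort(reports, lex,
                            strict_single_suspect = TRUE)$report_ids, "2")
})

test_that("therapy start dates fill in missing drug start dates", {
  demo <- raw_demo(primaryid = 1, caseid = 1, event_dt = "20230110")
  drug <- raw_drug(primaryid = 1, drugname = "X", start_dt = "")
  ther <- data.frame(PRIMARYID = "1", DSG_DRUG_SEQ = "1",
                     START_DT = "20230201", END_DT = "",
                     stringsAsFactors = FALSE)
  reports <- assemble_reports(parse_faers_records(demo, "DEMO"),
                              parse_faers_records(drug, "DRUG"),
                              parse_faers_records(raw_reac(1, "PT1"), "REAC"),
                              ther = parse_faers_records(ther, "THER"))
  expect_equal(reports$drugs$start_dt, "20230201")
  # and the merged date participates in chronology filtering
  res <- chronology_filter(reports)
  expect_equal(res$dropped$reason, "chronology")
})

test_that("the cleaning manifest reconciles counts at every step", {
  gen <- generate_faers(synthetic_config(seed = 5, n_reports = 800))
  parsed <- lapply(stats::setNames(nm = names(gen$tables)), function(k)
    parse_faers_records(gen$tables[[k]], k))
  res <- clean_reports(parsed$DEMO, parsed$DRUG, parsed$REAC,
                       outc = parsed$OUTC, ther = parsed$THER,
                       deleted = parsed$DELETED)
  m <- res$manifest
  expect_equal(m$n_in - m$n_out, m$n_dropped)
  expect_equal(m$n_out[1:2], m$n_in[2:3])
  expect_equal(m$n_dropped[1], gen$n_duplicates)
  expect_equal(m$n_dropped[2], gen$n_deleted)
})
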