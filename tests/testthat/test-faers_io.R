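test_that("reading binds columns by header name, not position", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CASEID$FDA_DT$PRIMARYID$SEX$EXTRA",
               "1$20230101$1001$F$x",
               "2$20230301$1002$M$y",
               "3$20230215$1003$$z"), path)
  demo <- read_faers_table(path, "DEMO")
  expect_equal(nrow(demo), 3)
  expect_equal(demo$primaryid, c("1001", "1002", "1003"))
  expect_equal(demo$caseid, c("1", "2", "3"))
  expect_equal(demo$sex, c("F", "M", "unknown"))
  expect_equal(demo$fda_dt_prec, rep("day", 3))
  expect_false("EXTRA" %in% names(demo))
})

test_that("drug role codes map to the FAERS vocabulary", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$drugname$role_cod",
               "1$AMOXICILLIN$PS",
               "2$AMOXICILLIN$SS",
               "3$AMOXICILLIN$C",
               "4$AMOXICILLIN$I",
               "5$AMOXICILLIN$ZZ"), path)
  drug <- read_faers_table(path, "DRUG")
  expect_equal(drug$role_code, c("PS", "SS", "C", "I", "unknown"))
})

test_that("header-only files give empty record sets", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("PRIMARYID$CASEID$FDA_DT", path)
  demo <- read_faers_table(path, "DEMO")
  expect_equal(nrow(demo), 0)
  expect_true(all(c("primaryid", "caseid", "fda_dt_prec") %in% names(demo)))
})

test_that("a missing mandatory column is a hard error naming the column", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRIMARYID$FDA_DT", "1$20230101"), path)
  expect_error(read_faers_table(path, "DEMO"), "CASEID")
})

test_that("malformed lines are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRIMARYID$PT",
               "1$Urticaria",
               "broken line with $ too $ many $ fields",
               "2$Rash"), path)
  expect_message(reac <- read_faers_table(path, "REAC"), "skipped 1")
  expect_equal(nrow(reac), 2)
  expect_equal(attr(reac, "n_skipped"), 1L)
})

test_that("write/read round-trips every parsed field", {
  gen <- generate_faers(synthetic_config(seed = 11, n_reports = 150))
  for (kind in c("DEMO", "DRUG", "REAC", "OUTC", "THER", "DELETED")) {
    path <- withr::local_tempfile(fileext = ".txt")
    first <- parse_faers_records(gen$tables[[kind]], kind)
    write_faers_table(first, path, kind)
    second <- read_faers_table(path, kind)
    attr(second, "n_skipped") <- NULL
    expect_equal(second, first, ignore_attr = FALSE, label = kind)
  }
})

test_that("reading is order-preserving and deterministic", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRIMARYID$PT", "3$C", "1$A", "2$B"), path)
  r1 <- read_faers_table(path, "REAC")
  r2 <- read_faers_table(path, "REAC")
  expect_equal(r1$primaryid, c("3", "1", "2"))
  expect_identical(r1, r2)
})

test_that("lexicon matching is exact-normalized with exclusions", {
  lex <- drug_lexicon("Amoxicillin",
                      synonyms = c("amoxicillin", "amoxicillin trihydrate"),
                      exclusions = "amoxicillin and clavulanate potassium")
  expect_true(lexicon_match("AMOXICILLIN", "", lex))
  expect_true(lexicon_match("  Amoxicillin ", "", lex))
  # exact match, not substring
  expect_false(lexicon_match("AMOXICILLIN AND CLAVULANATE POTASSIUM", "", lex))
  expect_false(lexicon_match("AMOXICILLIN SODIUM", "", lex))
  # the active-ingredient field can match even when the name does not
  expect_true(lexicon_match("BRANDNAME", "AMOXICILLIN", lex))
  # an exclusion on either field vetoes a synonym hit on the other
  expect_false(lexicon_match("AMOXICILLIN",
                             "Amoxicillin and Clavulanate Potassium", lex))
})

test_that("lexicon files parse sections and reject overlap", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[target]", "Amoxicillin", "[synonyms]", "amoxicillin",
               "Amoxicillin trihydrate  # trailing comment",
               "[exclusions]", "amoxicillin/clavulanate"), path)
  lex <- read_lexicon(path)
  expect_equal(lex$target_label, "Amoxicillin")
  expect_equal(length(lex$synonyms), 2)
  expect_equal(lex$exclusions, "AMOXICILLIN CLAVULANATE")
  expect_error(drug_lexicon("x", "a", "a"), "overlap")
  expect_error(drug_lexicon("x", character(0)), "synonym")
})

test_that("SOC mapping normalizes keys, merges duplicates, allows multi-SOC", {
  m <- soc_mapping(pt = c("Urticaria", "URTICARIA", "Hepatitis", "Hepatitis"),
                   soc = c("Skin and subcutaneous tissue disorders",
                           "Skin and subcutaneous tissue disorders",
                           "Hepatobiliary disorders",
                           "Immune system disorders"))
  expect_equal(soc_lookup(m, "URTICARIA ")[[1]],
               "Skin and subcutaneous tissue disorders")
  expect_setequal(soc_lookup(m, "hepatitis")[[1]],
                  c("Hepatobiliary disorders", "Immune system disorders"))
  # unmapped PT is an explicit empty result, not an error
  expect_equal(soc_lookup(m, "Nausea")[[1]], character(0))
  expect_error(soc_mapping("Rash", ""), "empty SOC")
})

test_that("SOC mapping files read as tab-separated PT/SOC pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PT\tSOC",
               "Urticaria\tSkin and subcutaneous tissue disorders",
               "Urticaria\tImmune system disorders"), path)
  m <- read_soc_mapping(path)
  expect_setequal(soc_lookup(m, "Urticaria")[[1]],
                  c("Skin and subcutaneous tissue disorders",
                    "Immune system disorders"))
})
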