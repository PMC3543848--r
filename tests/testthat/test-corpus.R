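test_that("JSONL corpora load, validate and round-trip", {
  co <- fixture_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path)
  co2 <- read_corpus(path, "jsonl")
  expect_s3_class(co2, "corpus")
  expect_length(co2$records, 5)
  expect_equal(doc_ids(co2), doc_ids(co))
  expect_equal(co2$records[[1]]$subject_headings,
               co$records[[1]]$subject_headings)
  ## missing abstracts are tolerated (letters often lack one)
  expect_identical(co2$records[[5]]$abstract, "")
})

test_that("duplicate doc_id in a corpus file is a validation error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","title":"one","relevant":true}',
               '{"doc_id":"a","title":"two","relevant":false}'), path)
  expect_error(read_corpus(path, "jsonl"), "duplicate doc_id.*1.*2")
})

test_that("invalid records are reported with their line numbers", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","title":"fine"}',
               '{"title":"no id"}',
               '{"doc_id":"c","pub_year":1700}'), path)
  err <- tryCatch(read_corpus(path, "jsonl"), error = conditionMessage)
  expect_match(err, "line 2")
  expect_match(err, "line 3")
})

test_that("excluded publication categories are dropped behind the flag", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","title":"keep","pub_type":"article"}',
               '{"doc_id":"b","title":"drop","pub_type":"erratum"}',
               '{"doc_id":"c","title":"drop2","pub_type":"book series"}'),
             path)
  expect_length(read_corpus(path, "jsonl")$records, 1)
  expect_length(read_corpus(path, "jsonl", drop_excluded = FALSE)$records, 3)
})

test_that("CSV and RIS-like dialects import equivalent records", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("doc_id,title,abstract,subject_headings,accessions,pub_year,source_dbs,relevant,pub_type",
               'x1,Off label use,An abstract,h1;h2,17872714;2007205136,2007,EMBASE;MEDLINE,true,article'),
             csv)
  co <- read_corpus(csv, "csv")
  expect_equal(co$records[[1]]$accessions, c("17872714", "2007205136"))
  expect_equal(co$records[[1]]$source_dbs, c("EMBASE", "MEDLINE"))
  expect_true(co$records[[1]]$relevant)

  ris <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ID - x1", "TI - Off label use", "AB - An abstract",
               "KW - h1", "KW - h2", "AN - 17872714", "PY - 2007",
               "DB - EMBASE", "RL - true", "ER -"), ris)
  co2 <- read_corpus(ris, "ris")
  expect_equal(co2$records[[1]]$title, "Off label use")
  expect_equal(co2$records[[1]]$subject_headings, c("h1", "h2"))
})

test_that("corpus load recovers the generator's planted relevant count", {
  gen <- generate_corpus(generator_config(n_docs = 50, seed = 11))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(gen$corpus, path)
  co <- read_corpus(path, "jsonl")
  n_rel <- sum(vapply(co$records, function(r) r$relevant, logical(1)))
  expect_equal(n_rel, gen$manifest$n_relevant)
})

test_that("records sharing an accession merge into one cluster", {
  co <- corpus(list(
    document_record("a", title = "Study by Caron", pub_year = 2007,
                    accessions = c("17872714"), relevant = TRUE),
    document_record("b", title = "Study by Caron", pub_year = 2007,
                    accessions = c("17872714", "2007205136"),
                    relevant = TRUE),
    document_record("c", title = "Unrelated", pub_year = 2008,
                    accessions = "999", relevant = FALSE)))
  dd <- dedup_records(co)
  expect_length(dd$corpus$records, 2)
  expect_equal(sum(dd$report$cluster_id == 1), 2)
  surv <- dd$corpus$records[[1]]
  expect_setequal(surv$accessions, c("17872714", "2007205136"))
})

test_that("title+year variants merge; corpora without shared keys pass through", {
  co <- corpus(list(
    document_record("a", title = "Colchicine in dermatology!",
                    pub_year = 2010, accessions = "1", relevant = TRUE),
    document_record("b", title = "colchicine in  dermatology",
                    pub_year = 2010, accessions = "2", relevant = TRUE)))
  dd <- dedup_records(co)
  expect_length(dd$corpus$records, 1)
  expect_equal(dd$report$reason, rep("title+year match", 2))

  clean <- fixture_corpus()
  dd2 <- dedup_records(clean)
  expect_length(dd2$corpus$records, length(clean$records))
  expect_equal(nrow(dd2$report), 0)
})

test_that("conflicting relevance labels are never silently merged", {
  co <- corpus(list(
    document_record("a", title = "Same", pub_year = 2000,
                    accessions = "1", relevant = TRUE),
    document_record("b", title = "Same", pub_year = 2000,
                    accessions = "1", relevant = FALSE)))
  expect_error(dedup_records(co), "conflicting relevance")
})

test_that("planted duplicate pairs and triplicates are recovered and dedup is idempotent", {
  gen <- generate_corpus(generator_config(n_docs = 100, seed = 3,
                                          duplicate_rate = 0.1,
                                          n_triplicates = 1))
  expect_length(gen$corpus$records, 100 + 10 + 2)
  dd <- dedup_records(gen$corpus)
  sizes <- table(table(dd$report$cluster_id))
  expect_equal(unname(sizes[["2"]]), 10)
  expect_equal(unname(sizes[["3"]]), 1)
  expect_length(dd$corpus$records, 100)
  ## idempotence and label preservation
  dd2 <- dedup_records(dd$corpus)
  expect_equal(nrow(dd2$report), 0)
  expect_equal(doc_ids(dd2$corpus), doc_ids(dd$corpus))
  n_rel_before <- sum(vapply(dd$corpus$records, function(r) r$relevant,
                             logical(1)))
  expect_equal(length(gold_from_corpus(dd$corpus)$full_set), n_rel_before)
})

test_that("year stratification is a partition matching the known histogram", {
  gen <- generate_corpus(generator_config(n_docs = 300, seed = 5))
  co <- gen$corpus
  strata <- stratify_by_year(co, list(c(1988, 2000), c(2001, 2011)))
  sizes <- vapply(strata, function(s) length(s$records), integer(1))
  expect_equal(sum(sizes), length(co$records))
  years <- vapply(co$records, function(r) r$pub_year, integer(1))
  expect_equal(unname(sizes["1988-2000"]),
               sum(years >= 1988 & years <= 2000))
  expect_equal(unname(sizes["2001-2011"]),
               sum(years >= 2001 & years <= 2011))
  ## pairwise disjoint
  ids <- lapply(strata, doc_ids)
  expect_equal(anyDuplicated(unlist(ids)), 0)
})

test_that("stratification rejects overlap and handles empty corpora", {
  co <- fixture_corpus()
  expect_error(stratify_by_year(co, list(c(1990, 2000), c(2000, 2010))),
               "overlap")
  empty <- corpus(list(), name = "empty")
  strata <- stratify_by_year(empty, list(c(1988, 2000)))
  expect_true(all(vapply(strata, function(s) length(s$records) == 0,
                         logical(1))))
})

test_that("gold standards enforce subset and non-emptiness invariants", {
  expect_error(gold_standard(c("a", "b"), c("c")), "subset")
  expect_error(gold_standard(character(0), character(0)), "non-empty")
  g <- gold_from_corpus(fixture_corpus())
  expect_setequal(g$full_set, c("d1", "d3", "d5"))
  expect_true(all(g$internal_set %in% g$full_set))
})
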