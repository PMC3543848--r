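test_that("truncation and hyphen-insensitive matching retrieve as expected", {
  co <- fixture_corpus()
  ## "off label*" prefix-matches the hyphen-normalized title of d1
  expect_true("d1" %in% evaluate_query("off label*.af.", co)$doc_ids)
  ## wildcard ? covers licence/license spelling variants
  hits <- evaluate_query("off li?en?e*.af.", co)$doc_ids
  expect_true(all(c("d3", "d5") %in% hits))
  ## untruncated phrase misses plural/derived forms the truncation catches
  plain <- evaluate_query("off label.af.", co)$doc_ids
  trunc <- evaluate_query("off label*.af.", co)$doc_ids
  expect_true(all(plain %in% trunc))
})

test_that("any query on an empty corpus retrieves nothing", {
  empty <- corpus(list(), name = "empty")
  expect_length(evaluate_query("off label*.af.", empty)$doc_ids, 0)
  expect_length(evaluate_query("(a adj2 b).mp.", empty)$doc_ids, 0)
})

test_that("field scopes distinguish headings from abstract/title text", {
  rec <- document_record("h1", title = "something else entirely",
                         subject_headings = "off label drug use",
                         relevant = TRUE)
  co <- corpus(list(rec))
  expect_equal(evaluate_query("(off adj2 label*).mp.", co)$doc_ids, "h1")
  expect_length(evaluate_query("(off adj2 label*).ab,ti.", co)$doc_ids, 0)
  ## .sh. is an exact whole-heading match, not a substring match
  expect_equal(evaluate_query('"off label drug use".sh.', co)$doc_ids, "h1")
  expect_length(evaluate_query('"off label".sh.', co)$doc_ids, 0)
})

test_that("adjacency windows respect distance, order-freedom and field boundaries", {
  co <- corpus(list(
    document_record("a", title = "label of the unapproved off use"),
    document_record("b", title = "off one two label"),
    document_record("c", title = "label something off"),
    document_record("d", title = "off", abstract = "label")))
  ## adjN: at most N-1 intervening tokens, either order
  expect_setequal(evaluate_query("(off adj2 label).ti.", co)$doc_ids, "c")
  expect_setequal(evaluate_query("(off adj3 label).ti.", co)$doc_ids,
                  c("b", "c"))
  expect_setequal(evaluate_query("(off adj4 label).ti.", co)$doc_ids,
                  c("a", "b", "c"))
  ## proximity never crosses field instances
  expect_length(evaluate_query("(off adj5 label).mp.", co)$doc_ids, 3)
})

test_that("scope monotonicity: ab < ab,ti < mp < af for the same pattern", {
  set.seed(21)
  for (seed in 1:5) {
    co <- rand_corpus(60, seed)
    idx <- corpus_index(co)
    for (pat in c("off label*", "stent*", "licen?e", "use*")) {
      ab <- evaluate_query(paste0(pat, ".ab."), idx)$doc_ids
      abti <- evaluate_query(paste0(pat, ".ab,ti."), idx)$doc_ids
      mp <- evaluate_query(paste0(pat, ".mp."), idx)$doc_ids
      af <- evaluate_query(paste0(pat, ".af."), idx)$doc_ids
      expect_true(all(ab %in% abti))
      expect_true(all(abti %in% mp))
      expect_true(all(mp %in% af))
    }
  }
})

test_that("truncation dominance and adjN nesting hold on random corpora", {
  for (seed in 1:5) {
    co <- rand_corpus(60, seed + 100)
    idx <- corpus_index(co)
    plain <- evaluate_query("off label.af.", idx)$doc_ids
    trunc <- evaluate_query("off label*.af.", idx)$doc_ids
    expect_true(all(plain %in% trunc))
    for (n in 1:4) {
      a <- evaluate_query(sprintf("(drug adj%d label*).af.", n), idx)$doc_ids
      b <- evaluate_query(sprintf("(drug adj%d label*).af.", n + 1),
                          idx)$doc_ids
      expect_true(all(a %in% b))
    }
  }
})

test_that("boolean operators obey set algebra", {
  for (seed in 1:4) {
    co <- rand_corpus(50, seed + 200)
    idx <- corpus_index(co)
    A <- evaluate_query("label*.af.", idx)$doc_ids
    B <- evaluate_query("stent*.af.", idx)$doc_ids
    AorB <- evaluate_query("(label* or stent*).af.", idx)$doc_ids
    AandB <- evaluate_query("(label* and stent*).af.", idx)$doc_ids
    AnotB <- evaluate_query("(label* not stent*).af.", idx)$doc_ids
    expect_equal(length(AorB), length(A) + length(B) - length(AandB))
    expect_length(intersect(AnotB, B), 0)
    expect_setequal(union(AnotB, AandB), A)
  }
})

test_that("engine agrees with the brute-force oracle on fixed and random queries", {
  queries <- c("off label*.af.", "(off adj2 label*).mp.",
               "off li?en?e*.af.", "(drug adj2 label adj2 us*).af.",
               "(label* not stent*).af.", '"off label drug use".sh.',
               "(us* adj3 veterinar*).ti.", "label-free.ab.")
  for (seed in 1:4) {
    co <- rand_corpus(40, seed + 300)
    for (q in queries) {
      expect_setequal(evaluate_query(q, co)$doc_ids,
                      oracle_retrieve(q, co))
    }
  }
})

test_that("strategy evaluation resolves line references and cumulates", {
  co <- fixture_corpus()
  ## self-union: (or/1-1) equals line 1
  res <- evaluate_strategy(c("off label*.af.", "(or/1-1)"), co)
  expect_setequal(res$sets[[2]]$doc_ids, res$sets[[1]]$doc_ids)
  ## disjoint single-term queries: cumulative counts are partial sums
  co2 <- corpus(list(document_record("x1", title = "alpha"),
                     document_record("x2", title = "beta"),
                     document_record("x3", title = "gamma")))
  res2 <- evaluate_strategy(c("alpha.ti.", "beta.ti.", "gamma.ti."), co2)
  expect_equal(vapply(res2$cumulative, function(s) length(s$doc_ids),
                      integer(1)), 1:3)
  ## NOT clause strictly shrinks the cumulative set when decoys are planted
  co3 <- corpus(c(fixture_corpus()$records,
                  list(document_record("s1",
                                       title = "off label stent use"))))
  res3 <- evaluate_strategy(
    c("off label*.af.", "unlicensed.af.",
      "(or/1-2) not (stent* or veterinar*).af."), co3)
  expect_lt(length(res3$sets[[3]]$doc_ids),
            length(res3$cumulative[[2]]$doc_ids))
  expect_false("s1" %in% res3$sets[[3]]$doc_ids)
})

test_that("unresolvable line references fail loudly", {
  co <- fixture_corpus()
  expect_error(evaluate_query("(or/1-3)", co), "line")
  expect_error(evaluate_strategy(c("(or/1-2)", "off label*.af."), co),
               "earlier")
})

test_that("accessions and publication type are searchable only under .af.", {
  co <- fixture_corpus()
  expect_equal(evaluate_query("1000002.af.", co)$doc_ids, "d2")
  expect_length(evaluate_query("1000002.mp.", co)$doc_ids, 0)
  expect_equal(evaluate_query("letter.af.", co)$doc_ids, "d5")
})
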