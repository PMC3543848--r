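make_pool <- function(sets, full, internal = full) {
  candidate_pool(sets, gold_standard(full, internal))
}

test_that("cumulative OR tables accumulate counts and marginal gains", {
  full <- sprintf("g%02d", 1:20)
  q1 <- c(full[1:8], "n1", "n2")              # 8 relevant of 10
  q2 <- c(full[9:12], "n3")                   # 4 new relevant of 5
  pool <- make_pool(list(q1 = q1, q2 = q2), full)
  tab <- cumulative_or_table(pool)
  expect_equal(tab$n_relevant_retrieved, c(8, 12))
  expect_equal(tab$sensitivity_full, c(40, 60))
  expect_equal(tab$new_relevant, c(8, 4))
  expect_equal(tab$new_retrieved, c(10, 5))
  ## a single query's table equals its performance row
  tab1 <- cumulative_or_table(make_pool(list(q1 = q1), full))
  row <- evaluate_performance(q1, gold_standard(full, full), label = "q1")
  expect_equal(tab1$precision, row$precision)
  expect_equal(tab1$n_retrieved, row$n_retrieved)
})

test_that("cumulative OR is monotone in relevant and total counts", {
  set.seed(31)
  for (rep in 1:10) {
    gen <- generate_retrieval_matrix(
      80, data.frame(p_rel = runif(6, 0.1, 0.9),
                     p_irrel = runif(6, 0, 0.4)),
      mode = "bernoulli", seed = rep)
    pool <- pool_from_matrix(gen$matrix, gen$relevant)
    tab <- cumulative_or_table(pool)
    expect_true(all(diff(tab$n_retrieved) >= 0))
    expect_true(all(diff(tab$n_relevant_retrieved) >= 0))
    expect_true(all(diff(tab$sensitivity_full) >= 0))
  }
})

test_that("a dominating query is selected alone", {
  full <- sprintf("g%02d", 1:10)
  pool <- make_pool(list(big = c(full, "x1"), small1 = full[1:3],
                         small2 = full[4:6]), full)
  expect_equal(maximize_sensitivity(pool, "greedy"), "big")
  expect_equal(maximize_sensitivity(pool, "exhaustive"), "big")
})

test_that("greedy-to-exhaustion attains the exhaustive coverage optimum", {
  for (seed in 1:25) {
    gen <- generate_retrieval_matrix(
      100, data.frame(p_rel = runif(8, 0.05, 0.7),
                      p_irrel = runif(8, 0, 0.3)),
      mode = "bernoulli", seed = 1000 + seed)
    pool <- pool_from_matrix(gen$matrix, gen$relevant)
    g <- maximize_sensitivity(pool, "greedy")
    e <- maximize_sensitivity(pool, "exhaustive", K = 8)
    cover <- function(sel) length(intersect(
      unique(unlist(pool$sets[sel])), pool$gold$full_set))
    expect_equal(cover(g), cover(e), label = paste("seed", seed))
    ## greedy order is reproducible and has strictly positive marginal gains
    tab <- cumulative_or_table(candidate_pool(pool$sets[g], pool$gold))
    expect_true(all(tab$new_relevant > 0))
  }
})

test_that("planted dominant query is picked first", {
  gen <- generate_retrieval_matrix(
    120, data.frame(p_rel = c(0.85, 0.2, 0.15, 0.1),
                    p_irrel = c(0.05, 0.02, 0.1, 0.01)),
    mode = "exact", seed = 4)
  pool <- pool_from_matrix(gen$matrix, gen$relevant)
  expect_equal(maximize_sensitivity(pool, "greedy")[1], "q1")
})

test_that("frontier equals the brute-force Pareto set on small pools", {
  brute_pareto <- function(pool) {
    m <- length(pool$labels)
    rows <- do.call(rbind, lapply(seq_len(2^m - 1), function(mask) {
      labels <- pool$labels[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      u <- unique(unlist(pool$sets[labels]))
      k <- length(intersect(u, pool$gold$full_set))
      data.frame(s = 100 * k / length(pool$gold$full_set),
                 p = 100 * k / length(u))
    }))
    keep <- vapply(seq_len(nrow(rows)), function(i) {
      !any(rows$s >= rows$s[i] & rows$p >= rows$p[i] &
             (rows$s > rows$s[i] | rows$p > rows$p[i]))
    }, logical(1))
    unique(rows[keep, ])
  }
  for (seed in 1:8) {
    gen <- generate_retrieval_matrix(
      60, data.frame(p_rel = runif(5, 0.1, 0.9),
                     p_irrel = runif(5, 0, 0.5)),
      mode = "bernoulli", seed = 500 + seed)
    pool <- pool_from_matrix(gen$matrix, gen$relevant)
    fr <- enumerate_frontier(pool, cap = 5)
    expected <- brute_pareto(pool)
    got <- unique(data.frame(s = fr$points$sensitivity_full,
                             p = fr$points$precision))
    expect_equal(nrow(got), nrow(expected), label = paste("seed", seed))
    expect_setequal(paste(round(got$s, 9), round(got$p, 9)),
                    paste(round(expected$s, 9), round(expected$p, 9)))
    ## frontier points are pairwise non-dominated
    pts <- fr$points
    for (i in seq_len(nrow(pts))) {
      dom <- pts$sensitivity_full >= pts$sensitivity_full[i] &
        pts$precision >= pts$precision[i] &
        (pts$sensitivity_full > pts$sensitivity_full[i] |
           pts$precision > pts$precision[i])
      expect_false(any(dom))
    }
  }
})

test_that("one strictly dominating query collapses the frontier", {
  full <- sprintf("g%02d", 1:10)
  pool <- make_pool(list(good = full, bad = c(full[1:2], "x1", "x2")), full)
  fr <- enumerate_frontier(pool)
  expect_equal(nrow(fr$points), 1)
  expect_equal(fr$points$sensitivity_full, 100)
  expect_equal(fr$points$precision, 100)
})

test_that("greedy prefixes are never strictly dominated by the frontier-free region", {
  gen <- generate_retrieval_matrix(
    80, data.frame(p_rel = c(0.7, 0.4, 0.3, 0.2, 0.1),
                   p_irrel = c(0.1, 0.05, 0.15, 0.02, 0.01)),
    mode = "exact", seed = 12)
  pool <- pool_from_matrix(gen$matrix, gen$relevant)
  fr <- enumerate_frontier(pool, cap = 5)
  sel <- maximize_sensitivity(pool, "greedy")
  for (k in seq_along(sel)) {
    u <- unique(unlist(pool$sets[sel[1:k]]))
    kk <- length(intersect(u, pool$gold$full_set))
    s <- 100 * kk / length(pool$gold$full_set)
    p <- 100 * kk / length(u)
    strictly_dom <- any(fr$points$sensitivity_full >= s &
                          fr$points$precision >= p &
                          (fr$points$sensitivity_full > s |
                             fr$points$precision > p))
    on_frontier <- any(abs(fr$points$sensitivity_full - s) < 1e-9 &
                         abs(fr$points$precision - p) < 1e-9)
    expect_true(strictly_dom || on_frontier)
  }
})

test_that("best trade-off minimizes distance to the ideal point", {
  fr <- data.frame(subset_labels = c("A", "B"),
                   sensitivity_full = c(94.0, 89.4),
                   precision = c(69.5, 87.4))
  pick <- best_tradeoff(fr, "distance")
  ## distances: A ~ sqrt(6^2 + 30.5^2) = 31.08; B ~ sqrt(10.6^2+12.6^2)=16.47
  expect_equal(pick$subset_labels, "B")
  expect_equal(pick$criterion_value,
               sqrt((100 - 89.4)^2 + (100 - 87.4)^2))
  ## singleton frontier returns itself
  single <- best_tradeoff(fr[1, ], "distance")
  expect_equal(single$subset_labels, "A")
})

test_that("trade-off criteria are optimal under brute-force scan, ties to sensitivity", {
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    s <- sort(runif(n, 50, 100), decreasing = TRUE)
    p <- sort(runif(n, 50, 100))
    fr <- data.frame(subset_labels = letters[1:n],
                     sensitivity_full = s, precision = p)
    pick <- best_tradeoff(fr, "distance")
    d <- sqrt((100 - s)^2 + (100 - p)^2)
    expect_equal(pick$criterion_value, min(d))
    pick_f1 <- best_tradeoff(fr, "f1")
    expect_equal(pick_f1$criterion_value, max(2 * s * p / (s + p)))
    k <- best_tradeoff(fr, "knee")
    expect_true(k$subset_labels %in% fr$subset_labels)
  }
  tie <- data.frame(subset_labels = c("lo", "hi"),
                    sensitivity_full = c(80, 90),
                    precision = c(90, 80))
  expect_equal(best_tradeoff(tie, "distance")$subset_labels, "hi")
})

test_that("NOT refinement removes planted decoys and reports deltas", {
  set.seed(10)
  mk <- function(i, title, rel)
    document_record(sprintf("n%03d", i), title = title, relevant = rel)
  recs <- c(
    lapply(1:40, function(i) mk(i, "off label use study", TRUE)),
    lapply(41:70, function(i) mk(i, "off label stent report", FALSE)),
    lapply(71:78, function(i) mk(i, "off label veterinary case", FALSE)),
    lapply(79:80, function(i) mk(i, "plain filler record", FALSE)))
  co <- corpus(recs)
  gold <- gold_from_corpus(co)
  ref <- not_refinement("off label*.af.", co, gold,
                        c("stent*", "veterinar*", "absentterm*"))
  expect_setequal(ref$selected_terms, c("stent*", "veterinar*"))
  expect_equal(ref$after$n_retrieved, ref$before$n_retrieved - 38)
  expect_equal(ref$after$precision, 100)
  expect_equal(unname(ref$delta["sensitivity_full"]), 0)
  expect_gt(unname(ref$delta["precision"]), 0)
  ## terms absent from the retrieved set change nothing
  ref2 <- not_refinement("off label*.af.", co, gold, "absentterm*")
  expect_length(ref2$selected_terms, 0)
  expect_equal(ref2$after$n_retrieved, ref2$before$n_retrieved)
  ## a NOT clause never increases sensitivity or retrieved count
  expect_lte(ref$after$n_retrieved, ref$before$n_retrieved)
  expect_lte(ref$after$sensitivity_full, ref$before$sensitivity_full)
})

test_that("the balanced strategy's NOT line yields the published 5.32-point precision gain", {
  before <- performance_from_counts(3650, 4446, 4067, 3846)
  after <- performance_from_counts(3635, 4158, 4067, 3846)
  gain <- round_half_up(after$precision, 2) -
    round_half_up(before$precision, 2)
  expect_equal(gain, 5.32)
  ## sensitivity cost: 0.37 overall, 0.39 within database
  expect_equal(round_half_up(before$sensitivity_full, 2) -
                 round_half_up(after$sensitivity_full, 2), 0.37)
  expect_equal(round_half_up(before$sensitivity_internal, 2) -
                 round_half_up(after$sensitivity_internal, 2), 0.39)
})

test_that("selected strategies re-evaluate to their reported counts", {
  gen <- generate_corpus(generator_config(
    n_docs = 300, seed = 17,
    query_specs = list(
      list(query = "alphaone*.ti.", sensitivity = 0.7, precision = 0.9),
      list(query = "betatwo*.ti.", sensitivity = 0.4, precision = 0.8),
      list(query = "gammathree*.ti.", sensitivity = 0.2, precision = 0.95))))
  pool <- build_pool(c("alphaone*.ti.", "betatwo*.ti.", "gammathree*.ti."),
                     gen$corpus, gen$gold)
  sel <- maximize_sensitivity(pool, "greedy")
  tab <- cumulative_or_table(candidate_pool(pool$sets[sel], gen$gold))
  ## re-evaluate the serialized strategy lines from scratch
  res <- evaluate_strategy(as_strategy(sel), gen$corpus)
  n <- length(sel)
  expect_equal(length(res$cumulative[[n]]$doc_ids),
               tab$n_retrieved[n])
  expect_equal(length(intersect(res$cumulative[[n]]$doc_ids,
                                gen$gold$full_set)),
               tab$n_relevant_retrieved[n])
})
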