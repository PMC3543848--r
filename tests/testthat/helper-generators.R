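# Random corpora and random query trees for property-style tests.

RAND_VOCAB <- c("off", "label", "labels", "labeling", "use", "uses",
                "drug", "drugs", "stent", "stents", "veterinary",
                "licence", "license", "unlicensed", "indication",
                "indications", "approve", "unapproved", "filler",
                "records", "study", "trial", "cohort", "label-free")

rand_text <- function(n) paste(sample(RAND_VOCAB, n, replace = TRUE),
                               collapse = " ")

rand_corpus <- function(n_docs, seed) {
  set.seed(seed)
  recs <- lapply(seq_len(n_docs), function(i) {
    document_record(
      doc_id = sprintf("r%03d", i),
      title = rand_text(sample(3:8, 1)),
      abstract = if (runif(1) < 0.85) rand_text(sample(10:25, 1)) else "",
      subject_headings = if (runif(1) < 0.6)
        replicate(sample(1:3, 1), rand_text(sample(1:4, 1))) else character(0),
      accessions = sprintf("%07d", i),
      pub_year = sample(1988:2011, 1),
      source_dbs = "EMBASE",
      relevant = runif(1) < 0.5,
      pub_type = sample(c("article", "letter", "conference abstract"), 1))
  })
  corpus(recs, name = paste0("rand", seed))
}

RAND_PATTERNS <- c("off", "label*", "use*", "drug", "stent*", "veterinar*",
                   "licen?e", "li?en?e*", "un*", "indica#ion*", "labels",
                   "approve*", "filler", "rec*", "study")

rand_term <- function() {
  k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  hedgedev:::q_term(sample(RAND_PATTERNS, k))
}

# term-like subtree (legal inside adjN)
rand_termlike <- function(depth) {
  if (depth <= 0 || runif(1) < 0.6) return(rand_term())
  r <- runif(1)
  if (r < 0.5) {
    hedgedev:::q_adj(sample(1:5, 1), rand_termlike(depth - 1),
                     rand_termlike(depth - 1))
  } else {
    hedgedev:::q_or(lapply(seq_len(sample(2:3, 1)),
                           function(i) rand_termlike(depth - 1)))
  }
}

rand_query_tree <- function(depth = 3) {
  if (depth <= 0) return(rand_term())
  r <- runif(1)
  node <- if (r < 0.30) rand_termlike(depth - 1)
  else if (r < 0.55) hedgedev:::q_or(lapply(seq_len(sample(2:3, 1)),
                                            function(i)
                                              rand_query_tree(depth - 1)))
  else if (r < 0.75) hedgedev:::q_not(rand_query_tree(depth - 1),
                                      rand_query_tree(depth - 1))
  else if (r < 0.85) hedgedev:::q_and(list(rand_query_tree(depth - 1),
                                           rand_query_tree(depth - 1)))
  else rand_query_tree(depth - 1)
  if (runif(1) < 0.4)
    node <- hedgedev:::q_field(sample(c("af", "mp", "ab", "ti", "ab_ti"), 1),
                               node)
  node
}

# tiny fixed corpus used across example-based tests
fixture_corpus <- function() {
  corpus(list(
    document_record("d1", title = "Off-label prescribing of antipsychotics",
                    abstract = "a cohort study of off label drug use",
                    subject_headings = c("off label drug use", "psychiatry"),
                    accessions = "1000001", pub_year = 2009,
                    relevant = TRUE),
    document_record("d2", title = "Stent placement outcomes",
                    abstract = "drug eluting stents in practice",
                    accessions = "1000002", pub_year = 2005,
                    relevant = FALSE),
    document_record("d3", title = "Unlicensed use in pediatrics",
                    abstract = "off-licence prescribing was common",
                    accessions = "1000003", pub_year = 1995,
                    relevant = TRUE),
    document_record("d4", title = "Veterinary extra-label use",
                    abstract = "extra label use of veterinary drugs",
                    accessions = "1000004", pub_year = 2001,
                    relevant = FALSE),
    document_record("d5", title = "Letter on off-license topics",
                    abstract = "", pub_year = 2010,
                    accessions = "1000005",
                    relevant = TRUE, pub_type = "letter")))
}
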