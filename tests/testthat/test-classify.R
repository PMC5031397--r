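test_that("word-model training satisfies its count and prior invariants", {
  lib <- toy_trimmed(toy_world(seed = 1))
  m <- train_bayes(lib, k = 8L)
  expect_equal(sum(m$M), m$N)
  expect_true(all(m$m >= 0L))
  expect_true(all(m$m <= matrix(m$M, nrow(m$m), ncol(m$m), byrow = TRUE)))
  expect_equal(m$prior, (m$n_w + 0.5) / (m$N + 1))
  expect_true(all(m$prior > 0 & m$prior < 1))
  # sequences shorter than k are rejected with a log entry
  rec <- rbind(lib$records[, c("id", "desc", "seq", "qual")],
               nuc_records("tiny", "ACGTACG"))
  tax <- rbind(lib$taxonomy,
               data.frame(id = "tiny", order = "O", family = "F",
                          genus = "G", species = "G s"))
  m2 <- train_bayes(rec, k = 8L, taxonomy = tax)
  expect_equal(m2$log$id, "tiny")
  expect_equal(m2$N, nrow(lib$records))
})

test_that("a lone training sequence classifies to its species at confidence 1", {
  set.seed(2)
  s <- rand_dna(154)
  tax <- data.frame(id = "only", order = "O", family = "F", genus = "G",
                    species = "G one", stringsAsFactors = FALSE)
  m <- train_bayes(nuc_records("only", s), taxonomy = tax)
  cl <- classify_bayes(m, s)
  expect_equal(attr(cl, "accepted_taxon"), "G one")
  expect_equal(cl$confidence[cl$rank == "species"], 1.0)
})

test_that("training sequences of a separated library recover their species", {
  lib <- toy_trimmed(toy_world(seed = 5))
  m <- train_bayes(lib)
  calls <- classify_bayes_batch(m, lib$records$seq[seq(1, 27, by = 3)],
                                classifier_params(seed = 11))
  truth <- lib$taxonomy$species[match(lib$records$id[seq(1, 27, by = 3)],
                                      lib$taxonomy$id)]
  for (i in seq_along(calls)) {
    expect_equal(calls[[i]]$taxon[calls[[i]]$rank == "species"], truth[i])
    expect_gte(calls[[i]]$confidence[calls[[i]]$rank == "species"], 0.99)
  }
})

test_that("a half-and-half query splits species confidence but keeps genus", {
  # query Q: words 1..73 occur only in species A, words 74..145 only in B;
  # all 145 words are diagnostic and 19 are sampled per trial (odd), so no
  # trial can tie and genus confidence is exactly 1.
  set.seed(13)
  repeat {
    q <- rand_dna(152)
    if (length(unique(substring(q, 1:145, 8:152))) == 145) break
  }
  sa <- substr(q, 1, 80)
  sb <- substr(q, 74, 152)
  tax <- data.frame(id = c("A", "B"), order = "O", family = "F",
                    genus = "G", species = c("G alpha", "G beta"),
                    stringsAsFactors = FALSE)
  m <- train_bayes(nuc_records(c("A", "B"), c(sa, sb)), taxonomy = tax)
  cl <- classify_bayes(m, q, classifier_params(confidence = 0.8,
                                               bootstrap = 1000L, seed = 3))
  sp_conf <- cl$confidence[cl$rank == "species"]
  expect_lt(abs(sp_conf - 0.5), 0.1)
  expect_true(attr(cl, "accepted_rank") %in% c("genus"))
  expect_equal(cl$confidence[cl$rank == "genus"], 1.0)
})

test_that("confidence is monotone across ranks and calls are seed-reproducible", {
  lib <- toy_trimmed(toy_world(seed = 6))
  m <- train_bayes(lib)
  set.seed(21)
  queries <- vapply(sample(nrow(lib$records), 6), function(i) {
    ch <- strsplit(lib$records$seq[i], "")[[1]]
    pos <- sample(length(ch), 8)
    ch[pos] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  a <- classify_bayes_batch(m, queries, classifier_params(seed = 9))
  b <- classify_bayes_batch(m, queries, classifier_params(seed = 9))
  expect_identical(a, b)
  for (cl in a) {
    conf <- cl$confidence
    expect_true(all(diff(conf[!is.na(conf)]) >= 0))  # species -> order
  }
})

test_that("raising the threshold only moves calls toward unclassified", {
  lib <- toy_trimmed(toy_world(seed = 7))
  m <- train_bayes(lib)
  q <- lib$records$seq[5]
  lo <- classify_bayes(m, q, classifier_params(confidence = 0.5, seed = 2))
  hi <- classify_bayes(m, q, classifier_params(confidence = 1.0, seed = 2))
  expect_identical(lo$confidence, hi$confidence)  # same trials, new cut
  r_lo <- attr(lo, "accepted_rank"); r_hi <- attr(hi, "accepted_rank")
  depth <- function(r) match(r, c("species", "genus", "family", "order",
                                  "unclassified"))
  expect_gte(depth(r_hi), depth(r_lo))
})

test_that("leave-one-out species recovery on a separated world is >= 99%", {
  lib <- toy_trimmed(toy_world(seed = 10))
  n <- nrow(lib$records)
  correct <- 0L
  for (i in seq_len(n)) {
    train <- ref_library(lib$records[-i, ], lib$taxonomy[-i, ])
    m <- train_bayes(train)
    cl <- classify_bayes(m, lib$records$seq[i],
                         classifier_params(confidence = 0.5, seed = 4))
    truth <- lib$taxonomy$species[i]
    if (identical(attr(cl, "accepted_taxon"), truth)) correct <- correct + 1L
  }
  expect_gte(correct / n, 0.99)
})

test_that("top-hit classification assigns the deepest unanimous rank", {
  lib <- toy_trimmed(toy_world(seed = 12))
  q <- lib$records$seq[4]
  th <- classify_tophit(lib, q)
  expect_equal(th$best_identity, 1.0)
  expect_equal(th$rank, "species")
  expect_equal(th$taxon, lib$taxonomy$species[4])

  # exact tie between two genera resolves to their shared family
  set.seed(14)
  s <- rand_dna(154)
  tax <- data.frame(id = c("x", "y"), order = "O", family = "F",
                    genus = c("G1", "G2"),
                    species = c("G1 a", "G2 b"), stringsAsFactors = FALSE)
  th2 <- classify_tophit(nuc_records(c("x", "y"), c(s, s)), s,
                         taxonomy = tax)
  expect_equal(nrow(th2$ties), 2L)
  expect_equal(th2$rank, "family")
  expect_equal(th2$taxon, "F")
  expect_error(classify_tophit(nuc_records(character(), character()), s,
                               taxonomy = tax), "empty")
})

test_that("top-hit yields more false positives than Bayes on novel species", {
  # hold an entire species out of training: its sequences have no true
  # match, so species-level assignments are false positives by definition
  lib <- toy_trimmed(toy_world(seed = 15))
  hold <- lib$taxonomy$id[lib$taxonomy$species == "Genus01 species01"]
  keep <- !(lib$records$id %in% hold)
  train <- ref_library(lib$records[keep, ], lib$taxonomy[keep, ])
  m <- train_bayes(train)
  queries <- lib$records$seq[!keep]
  bayes_fp <- 0L; tophit_fp <- 0L
  for (q in queries) {
    cl <- classify_bayes(m, q, classifier_params(confidence = 0.8, seed = 5))
    if (attr(cl, "accepted_rank") == "species") bayes_fp <- bayes_fp + 1L
    th <- classify_tophit(train, q)
    if (identical(th$rank, "species")) tophit_fp <- tophit_fp + 1L
  }
  expect_gte(tophit_fp, bayes_fp)
  expect_gt(tophit_fp, 0L)
})

test_that("the word model survives JSON-lines serialization", {
  lib <- toy_trimmed(toy_world(seed = 16, n_genera = 2))
  m <- train_bayes(lib)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_bayes_model(m, f)
  m2 <- read_bayes_model(f)
  q <- lib$records$seq[3]
  expect_identical(classify_bayes(m, q, classifier_params(seed = 8)),
                   classify_bayes(m2, q, classifier_params(seed = 8)))
})
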