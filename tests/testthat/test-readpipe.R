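# Shared miniature pool used by several read-pipeline tests.
pool_fixture <- function(seed = 1L, n_pairs = 400L, quality = 33L,
                         props = c(0.5, 0.3, 0.2)) {
  w <- toy_world(seed = seed)
  sp <- w$taxonomy$species[!duplicated(w$taxonomy$genus)][seq_along(props)]
  names(props) <- sp
  pool <- simulate_pooled_reads(
    w, pool_spec(props, n_pairs = n_pairs, quality = quality,
                 seed = seed + 100L))
  list(world = w, pool = pool, species = sp,
       model = train_bayes(toy_trimmed(w)))
}

test_that("tail+primer stripping removes leading adapters and rejects others", {
  fx <- pool_fixture(seed = 2, n_pairs = 50, quality = 93)  # error-free
  pair <- fx$world$params$pair
  out <- strip_primers_tails(fx$pool$pairs, pair)
  expect_equal(nrow(out$pairs), 50L)
  # stripped forward mate = template insert prefix (no tail, no primer)
  tpl <- fx$pool$templates
  ins <- substr(tpl$product[match(fx$pool$truth$species[1], tpl$species)],
                27, 180)
  expect_equal(substr(out$pairs$seq1[1], 1, 20), substr(ins, 1, 20))
  # a read without the primer is rejected when required
  set.seed(3)
  junk <- fx$pool$pairs[1:3, ]
  junk$seq1[2] <- rand_dna(nchar(junk$seq1[2]))
  out2 <- strip_primers_tails(junk, pair)
  expect_equal(nrow(out2$pairs), 2L)
  expect_equal(out2$rejects$reason, "no_forward_primer")
})

test_that("pair merging reconstructs templates and resolves conflicts by quality", {
  set.seed(4)
  tmpl <- rand_dna(154)
  fwd <- substr(tmpl, 1, 100)
  rev <- reverse_complement(substr(tmpl, 55, 154))
  q40 <- phred_chars(rep(40, 100))
  m <- merge_pair(fwd, q40, rev, q40)
  expect_equal(m$seq, tmpl)
  expect_equal(m$overlap_length, 46L)
  expect_equal(m$overlap_mismatches, 0L)

  # planted conflict: fwd says A at Q40, rev says C at Q10 -> keep A, Q30
  fwd2 <- fwd
  conflict_pos <- 80L  # inside the 55..100 overlap
  substr(fwd2, conflict_pos, conflict_pos) <- "A"
  rev2chars <- strsplit(substr(tmpl, 55, 154), "")[[1]]
  rev2chars[conflict_pos - 54L] <- "C"
  rev2 <- reverse_complement(paste(rev2chars, collapse = ""))
  m2 <- merge_pair(fwd2, q40, rev2, phred_chars(rep(10, 100)))
  expect_equal(substr(m2$seq, conflict_pos, conflict_pos), "A")
  expect_equal(phred_ints(m2$qual)[conflict_pos], 30L)
  # agreement sums qualities, capped at 45
  expect_equal(phred_ints(m$qual)[60], 45L)

  # overlap below the minimum fails
  short_rev <- reverse_complement(substr(tmpl, 145, 154))
  expect_null(merge_pair(fwd, q40, short_rev, phred_chars(rep(40, 10)),
                         merge_params(min_overlap = 20)))

  # the vectorized batch agrees with the scalar merger
  fx <- pool_fixture(seed = 5, n_pairs = 30)
  stripped <- strip_primers_tails(fx$pool$pairs, fx$world$params$pair)
  batch <- merge_pairs(stripped$pairs)
  for (i in sample(nrow(stripped$pairs), 5)) {
    one <- merge_pair(stripped$pairs$seq1[i], stripped$pairs$qual1[i],
                      stripped$pairs$seq2[i], stripped$pairs$qual2[i])
    j <- match(stripped$pairs$id[i], batch$merged$id)
    expect_equal(batch$merged$seq[j], one$seq)
    expect_equal(batch$merged$qual[j], one$qual)
    expect_equal(batch$merged$overlap_length[j], one$overlap_length)
  }
})

test_that("screening drops ambiguous/miss-sized reads and dereplicates", {
  merged <- data.frame(
    id = sprintf("m%d", 1:6),
    seq = c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTNCGT",
            paste(rep("A", 48), collapse = ""), "ACGTACGA"),
    stringsAsFactors = FALSE)
  out <- screen_dereplicate(merged, screen_params(l_expected = 8, delta = 2))
  expect_equal(out$uniques$abundance, c(3L, 1L))
  expect_equal(out$uniques$seq[1], "ACGTACGT")
  expect_equal(sort(out$rejects$reason), c("ambiguous", "length"))
  # accounting: kept + rejected = input
  expect_equal(sum(out$uniques$abundance) + nrow(out$rejects), nrow(merged))
})

test_that("constructed bimeras are flagged with their parents", {
  set.seed(6)
  a <- rand_dna(202)
  b_chars <- strsplit(a, "")[[1]]
  flip <- sample(202, 24)
  b_chars[flip] <- vapply(b_chars[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  b <- paste(b_chars, collapse = "")
  chimera <- paste0(substr(a, 1, 100), substr(b, 101, 202))
  uniq <- data.frame(seq = c(a, b, chimera),
                     abundance = c(50L, 50L, 5L),
                     rep_id = c("pA", "pB", "chi"), stringsAsFactors = FALSE)
  out <- flag_chimeras(uniq)
  expect_false(out$chimera[1])   # abundant parents never flagged
  expect_false(out$chimera[2])
  expect_true(out$chimera[3])
  expect_setequal(c(out$parent_left[3], out$parent_right[3]), c("pA", "pB"))

  # a clean divergent sequence with no crossover gain is not flagged
  clean <- rbind(uniq[1:2, ],
                 data.frame(seq = rand_dna(202), abundance = 1L,
                            rep_id = "solo"))
  out2 <- flag_chimeras(clean)
  expect_false(any(out2$chimera))
})

test_that("zero-error pools reproduce template proportions exactly", {
  fx <- pool_fixture(seed = 7, n_pairs = 300, quality = 93,
                     props = c(0.6, 0.4))
  res <- run_read_pipeline(fx$pool$pairs, fx$world$params$pair, fx$model)
  acc <- res$accounting
  expect_equal(acc$stripped_kept, acc$merged + acc$merge_failures)
  expect_equal(acc$merged, acc$screened_kept + acc$screen_rejects)
  expect_equal(acc$merge_failures, 0L)
  expect_equal(acc$chimeras, 0L)
  # merged reads equal template inserts byte-for-byte
  inserts <- substr(fx$pool$templates$product, 27,
                    nchar(fx$pool$templates$product) - 22)
  expect_true(all(res$screened$uniques$seq %in% inserts))
  # output proportions equal template proportions exactly
  truth_counts <- table(fx$pool$truth$species)
  tab <- res$profile$table
  expect_equal(tab$reads[match(names(truth_counts), tab$species)],
               as.integer(truth_counts))
  expect_equal(sum(tab$proportion) +
                 res$profile$unclassified_reads / res$profile$total_reads, 1)
})

test_that("a single-species pool profiles to that species at proportion 1", {
  fx <- pool_fixture(seed = 8, n_pairs = 120, quality = 93, props = 1)
  res <- run_read_pipeline(fx$pool$pairs, fx$world$params$pair, fx$model)
  tab <- res$profile$table
  expect_equal(tab$species[tab$detected], fx$species[1])
  expect_equal(tab$proportion[1], 1.0)
})

test_that("detection is monotone in sequencing depth", {
  fx <- pool_fixture(seed = 9, n_pairs = 400, quality = 33)
  res <- run_read_pipeline(fx$pool$pairs, fx$world$params$pair, fx$model)
  detected1 <- res$profile$table$species[res$profile$table$detected]
  # doubling every unique's abundance at fixed proportions
  uniq2 <- res$uniques
  uniq2$abundance <- uniq2$abundance * 2L
  prof2 <- profile_pool(uniq2, fx$model)
  detected2 <- prof2$table$species[prof2$table$detected]
  expect_true(all(detected1 %in% detected2))
})
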