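test_that("site scoring weights mismatches by primer position", {
  p <- degenerate_primer("SFF_145f", "GTHACHGCYCAYGCHTTYGTAATAAT", "forward")
  perfect <- "GTAACAGCTCACGCATTCGTAATAAT"  # one expansion of the primer
  expect_equal(score_site(p, perfect)$weighted_score, 0)

  # one mismatch outside the 3' window (position 1: G -> C)
  w <- perfect
  substr(w, 1, 1) <- "C"
  expect_equal(score_site(p, w)$weighted_score, 0.4)

  # mismatch at the 3'-terminal base only (T -> C at position 26)
  w <- perfect
  substr(w, 26, 26) <- "C"
  s <- score_site(p, w)
  expect_equal(s$weighted_score, 3.0)
  expect_true(s$terminal_mismatch)
  expect_equal(s$mismatches_3, 1L)

  # non-terminal 3'-window mismatch (position 23, A -> C)
  w <- perfect
  substr(w, 23, 23) <- "C"
  expect_equal(score_site(p, w)$weighted_score, 1.0)

  expect_error(score_site(p, "ACGT"), "length")
})

test_that("reverse primers score against the plus strand via their rc", {
  # reverse primer footprint on the plus strand = rc(primer); its 3' end
  # sits at the LEFT of the footprint, so a mismatch there costs w_terminal
  pr <- degenerate_primer("SFF_351r", "CTCCWGCRTGDGCWAGRTTTCC", "reverse")
  fp <- "GGAAACCTAGCACATGCAGGAG"  # one expansion of rc(SFF_351r)
  expect_equal(score_site(pr, fp)$weighted_score, 0)
  w <- fp
  substr(w, 1, 1) <- "T"  # plus-strand position 1 = primer 3' terminus
  s <- score_site(pr, w)
  expect_equal(s$weighted_score, 3.0)
  expect_true(s$terminal_mismatch)
})

test_that("best-site scan finds embedded primers and matches brute force", {
  set.seed(3)
  p <- degenerate_primer("p", "GTHACHGCYCAYGCHTTYGTAATAAT", "forward")
  emb <- "GTAACAGCTCACGCATTCGTAATAAT"
  subj <- paste0(rand_dna(37), emb, rand_dna(50))
  s <- scan_best_site(p, subj)
  expect_equal(s$start, 37L)
  expect_equal(s$weighted_score, 0)
  expect_true(s$hit)

  # reverse primer located via reverse complement on the plus strand
  pr <- degenerate_primer("r", "CTCCWGCRTGDGCWAGRTTTCC", "reverse")
  subj2 <- paste0(rand_dna(20), "GGAAACCTAGCACATGCAGGAG", rand_dna(20))
  s2 <- scan_best_site(pr, subj2)
  expect_equal(s2$start, 20L)
  expect_equal(s2$weighted_score, 0)

  # oracle equivalence: enumerate expansions x offsets
  for (i in 1:25) {
    orient <- sample(c("forward", "reverse"), 1)
    pseq <- rand_primer(sample(16:24, 1), sample(0:4, 1))
    subj <- rand_dna(sample(80:200, 1))
    got <- scan_best_site(degenerate_primer("p", pseq, orient), subj)
    want <- oracle_best_site(pseq, orient, subj)
    expect_equal(got$weighted_score, want$score)
    expect_equal(got$start, want$start0)
  }
})

test_that("in-silico PCR extracts products with the inclusive length convention", {
  fwd_fp <- "GTAACAGCTCACGCATTCGTAATAAT"          # 26 nt SFF_145f footprint
  rev_fp <- "GGAAACCTAGCACATGCAGGAG"              # 22 nt rc(SFF_351r)
  set.seed(5)
  insert <- rand_dna(154)
  tmpl <- nuc_records("t1", paste0(rand_dna(30), fwd_fp, insert, rev_fp,
                                   rand_dna(25)))
  pair <- primer_pair("SFF_145f", "SFF_351r")
  hits <- insilico_pcr(pair, tmpl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, 202L)         # 26 + 154 + 22
  expect_equal(hits$insert, insert)
  expect_equal(nchar(hits$product),
               nchar(pair$forward$sequence) + nchar(hits$insert) +
                 nchar(pair$reverse$sequence))

  # template lacking a reverse site yields no amplicon, with a log entry
  tmpl2 <- nuc_records("t2", paste0(rand_dna(30), fwd_fp, rand_dna(100)))
  h2 <- insilico_pcr(pair, tmpl2)
  expect_equal(nrow(h2), 0L)
  expect_equal(attr(h2, "log")$reason, "no_reverse_site")

  # overlapping footprints (reverse site upstream of forward) rejected
  tmpl3 <- nuc_records("t3", paste0(rand_dna(10), rev_fp, rand_dna(5),
                                    fwd_fp, rand_dna(10)))
  h3 <- insilico_pcr(pair, tmpl3)
  expect_equal(nrow(h3), 0L)
})

test_that("product-length invariant holds across a simulated world", {
  w <- toy_world(seed = 4)
  hits <- insilico_pcr(w$params$pair, w$records)
  expect_equal(nrow(hits), nrow(w$records))
  expect_true(all(hits$product_length ==
                    nchar(hits$insert) + 26L + 22L))
})

test_that("de novo design recovers a planted conserved site", {
  set.seed(9)
  planted <- "GTAACAGCTCACGCATTCGTAATAAT"
  targets <- nuc_records(sprintf("t%02d", 1:20),
                         vapply(1:20, function(i) {
                           paste0(rand_dna(40), planted, rand_dna(60))
                         }, character(1)))
  cands <- design_primers(targets, NULL, design_params(primer_length = 26L))
  expect_gt(nrow(cands), 0L)
  expect_equal(cands$target_coverage[1], 1.0)
  expect_true(planted %in% cands$sequence)
  expect_true(all(cands$degeneracy <= 512))

  # the same site planted in an exclusion set ranks below a target-only one
  excl <- nuc_records("e1", paste0(rand_dna(30), planted, rand_dna(30)))
  cands2 <- design_primers(targets, excl, design_params(primer_length = 26L))
  expect_true(all(cands2$exclusion_coverage[cands2$sequence == planted] == 1))

  # no conserved seed -> empty with diagnostic
  set.seed(10)
  div <- nuc_records(c("a", "b", "c"),
                     c(rand_dna(80), rand_dna(80), rand_dna(80)))
  none <- design_primers(div, NULL,
                         design_params(seed_fraction = 1.0))
  expect_equal(nrow(none), 0L)
  expect_false(is.null(attr(none, "diagnostic")))
})

test_that("per-taxon coverage fractions aggregate amplification", {
  w <- toy_world(seed = 2)
  hits <- insilico_pcr(w$params$pair, w$records)
  cov <- taxon_coverage(hits, w$taxonomy, "genus")
  expect_true(all(cov$coverage == 1.0))
  expect_equal(attr(cov, "overall"), 1.0)

  none <- hits[0, , drop = FALSE]
  cov0 <- taxon_coverage(none, w$taxonomy, "genus")
  expect_true(all(cov0$coverage == 0))
  expect_equal(sum(cov0$n_total), nrow(w$records))
})
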