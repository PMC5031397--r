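test_that("FASTA I/O round-trips, normalizes case/U and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c(">r1 first record", "acgtu", ">r2", "GGGTTT"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("r1", "r2"))
  expect_equal(recs$seq[1], "ACGTT")
  expect_equal(recs$desc[1], "first record")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f2)
  expect_equal(read_fasta(f2), recs)

  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">empty", "", ">ok", "ACGT"), f)
  expect_error(read_fasta(f), "empty sequence")
})

test_that("FASTQ round-trip preserves sequence and quality bytes", {
  set.seed(42)
  recs <- nuc_records(paste0("q", 1:5),
                      replicate(5, rand_dna(60)),
                      qual = replicate(5, phred_chars(sample(0:41, 60, TRUE))))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(recs, f)
  back <- read_fastq(f)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$qual, recs$qual)
  expect_equal(phred_ints(back$qual[1]), phred_ints(recs$qual[1]))
})

test_that("BOLD-style lineages parse with subfamily dropped and validation", {
  l <- parse_bold_lineage("Chiroptera;Vespertilionidae;Myotis;Myotis velifer")
  expect_equal(unlist(l[c("order", "family", "genus", "species")],
                      use.names = FALSE),
               c("Chiroptera", "Vespertilionidae", "Myotis",
                 "Myotis velifer"))
  expect_false(l$incomplete)

  # five fields: subfamily accepted on input, dropped
  l5 <- parse_bold_lineage(
    "Chiroptera;Vespertilionidae;Myotinae;Myotis;Myotis velifer")
  expect_equal(l5$genus, "Myotis")
  expect_equal(l5$family, "Vespertilionidae")

  g <- parse_bold_lineage("Chiroptera;Vespertilionidae;Myotis;")
  expect_true(is.na(g$species))
  expect_true(g$incomplete)

  e <- parse_bold_lineage(";;;")
  expect_true(all(is.na(unlist(e[c("order", "family", "genus", "species")]))))
  expect_true(e$incomplete)

  expect_error(parse_bold_lineage(";;;Myotis velifer"), "without genus")
})

test_that("IUPAC base matching follows set intersection semantics", {
  expect_true(iupac_match("A", "H"))
  expect_false(iupac_match("G", "H"))
  expect_true(iupac_match("T", "Y"))
  expect_true(iupac_match("N", "A"))
  expect_true(all(iupac_match(c("A", "C", "G", "T"), "N")))
  expect_true(iupac_match("R", "K"))   # {A,G} and {G,T} share G
  expect_false(iupac_match("R", "Y"))  # {A,G} vs {C,T}
  expect_error(iupac_match("X", "A"), "non-IUPAC")
})

test_that("reverse complement is an IUPAC-aware involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  # reverse mini-barcode primer onto the plus strand
  expect_equal(reverse_complement("CTCCWGCRTGDGCWAGRTTTCC"),
               "GGAAAYCTWGCHCAYGCWGGAG")
  set.seed(7)
  for (i in 1:20) {
    x <- rand_primer(sample(15:40, 1), sample(0:6, 1))
    expect_equal(reverse_complement(reverse_complement(x)), x)
    expect_equal(degeneracy(reverse_complement(x)), degeneracy(x))
  }
})

test_that("pseudogene screen counts vertebrate-mitochondrial stops per frame", {
  # a stop lurks in every frame: TAA at offsets 0 (frame 0), 4 (frame 1)
  # and 8 (frame 2), so no frame choice can rescue the sequence
  expect_equal(pseudogene_screen("TAAATAAATAA")$status, "flagged")
  expect_error(pseudogene_screen("AC"), "codon")

  # auto frame equals brute-force argmin over literal translation
  set.seed(11)
  for (i in 1:25) {
    s <- rand_dna(sample(60:240, 1))
    got <- pseudogene_screen(s)
    want <- oracle_stop_counts(s)
    expect_equal(unname(got$per_frame), unname(want))
    expect_equal(got$chosen_frame, which.min(want) - 1L)
    expect_equal(got$status, if (want[got$chosen_frame + 1L] > 0) "flagged"
                             else "pass")
  }

  # degenerate codons: flagged only when every resolution is a stop
  expect_equal(pseudogene_screen("ATGTARGCA", frame = 0)$stop_count, 1L)
  expect_equal(pseudogene_screen("ATGTAMGCA", frame = 0)$stop_count, 0L)
  expect_equal(pseudogene_screen("ATGAGRGCA", frame = 0)$stop_count, 1L)
})

test_that("taxonomy TSV round-trips through the QIIME-style dialect", {
  tax <- data.frame(id = c("a", "b"),
                    order = c("Chiroptera", "Chiroptera"),
                    family = c("Vespertilionidae", NA),
                    genus = c("Myotis", NA),
                    species = c("Myotis velifer", NA),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f)
  expect_equal(read_taxonomy(f), tax)
})
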