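# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's scanning/clustering
# internals: the oracles enumerate, the implementation optimizes.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# All concrete ACGT expansions of an IUPAC string.
expand_degenerate <- function(seq) {
  sets <- IUPAC_SETS[strsplit(seq, "", fixed = TRUE)[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Position penalties recomputed from first principles (primer 5'->3').
oracle_penalties <- function(m, tw = 5L, w_non3 = 0.4, w_3 = 1.0,
                             w_terminal = 3.0) {
  p <- rep(w_non3, m)
  p[(m - min(tw, m) + 1L):m] <- w_3
  p[m] <- w_terminal
  p
}

# Brute-force best site: enumerate every expansion x every offset, score
# by exact character comparison. Reverse primers are expanded first, then
# each variant is reverse-complemented onto the plus strand with reversed
# penalties. Returns list(score, start0).
oracle_best_site <- function(primer_seq, orientation, subject) {
  m <- nchar(primer_seq)
  pen <- oracle_penalties(m)
  variants <- expand_degenerate(primer_seq)
  if (orientation == "reverse") {
    variants <- vapply(variants, function(v) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", v), "",
                         fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    pen <- rev(pen)
  }
  sch <- strsplit(subject, "", fixed = TRUE)[[1]]
  best <- list(score = Inf, start0 = NA_integer_)
  for (o in 0:(length(sch) - m)) {
    win <- sch[(o + 1L):(o + m)]
    for (v in variants) {
      sc <- sum(pen[win != strsplit(v, "", fixed = TRUE)[[1]]])
      if (sc < best$score) best <- list(score = sc, start0 = o)
    }
  }
  best
}

# Brute-force frame selection: count literal stop codons per frame.
oracle_stop_counts <- function(seq) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  vapply(0:2, function(f) {
    n <- nchar(seq) - f
    if (n < 3L) return(NA_integer_)
    starts <- seq.int(f + 1L, f + n - n %% 3L - 2L, by = 3L)
    sum(substring(seq, starts, starts + 2L) %in% stops)
  }, integer(1))
}

# Random ACGT string.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random IUPAC primer with bounded degeneracy.
rand_primer <- function(len = 20L, n_degenerate = 3L) {
  base <- strsplit(rand_dna(len), "", fixed = TRUE)[[1]]
  pos <- sample(len, n_degenerate)
  base[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "H", "D", "N"),
                      n_degenerate, replace = TRUE)
  paste(base, collapse = "")
}

# Small well-separated world shared by classifier/eval tests.
toy_world <- function(seed = 1L, n_genera = 3L) {
  simulate_reference_world(world_params(
    n_genera = n_genera, species_per_genus = 3L, seqs_per_species = 3L,
    seed = seed))
}

toy_trimmed <- function(world = toy_world()) {
  trim_to_minibarcode(world, world$params$pair)
}

# Evaluation-grade library: several haplotypes per species (within-species
# divergence at 1%), so a 5% holdout after 100%-identity dereplication
# leaves every species represented in training -- the database-richness
# regime the leave-out design assumes.
eval_world <- function(seed = 1L) {
  simulate_reference_world(world_params(
    n_genera = 4L, species_per_genus = 3L, seqs_per_species = 6L,
    d_within = 0.01, seed = seed))
}
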