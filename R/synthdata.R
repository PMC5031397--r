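# Seeded generator of COI-like reference worlds (hierarchical lineages with
# planted primer footprints, stop-free in frame 0 under the vertebrate
# mitochondrial code) and pooled paired-end amplicon read sets with known
# ground truth.

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .MITO_STOPS)
})

#' World-generation parameters
#'
#' Divergence targets are expected per-site substitution fractions between
#' two random members of the named level: `d_genus` between genera,
#' `d_species` between congeneric species, `d_within` within a species.
#'
#' @param n_genera number of genera.
#' @param species_per_genus species per genus.
#' @param seqs_per_species sequences per species.
#' @param root_length root sequence length in nt (coding, default 658).
#' @param d_genus,d_species,d_within divergence targets
#'   (`d_within < d_species < d_genus`).
#' @param pair planted primer pair; its footprints are substitution-free in
#'   every generated record.
#' @param fwd_start 1-based plus-strand start of the forward footprint.
#' @param insert_length nt between the footprints.
#' @param order_name order for all lineages.
#' @param genera_per_family genera grouped into each family.
#' @param seed RNG seed.
#' @return a `world_params` list.
#' @export
world_params <- function(n_genera = 4L, species_per_genus = 3L,
                         seqs_per_species = 3L, root_length = 658L,
                         d_genus = 0.12, d_species = 0.05, d_within = 0.005,
                         pair = primer_pair("SFF_145f", "SFF_351r"),
                         fwd_start = 145L, insert_length = 154L,
                         order_name = "Chiroptera", genera_per_family = 2L,
                         seed = 1L) {
  stopifnot(d_within < d_species, d_species < d_genus,
            n_genera >= 1L, species_per_genus >= 1L, seqs_per_species >= 1L)
  mf <- nchar(pair$forward$sequence)
  mr <- nchar(pair$reverse$sequence)
  if (fwd_start + mf + insert_length + mr - 1L > root_length) {
    stop("primer footprints + insert do not fit in root_length")
  }
  list(n_genera = as.integer(n_genera),
       species_per_genus = as.integer(species_per_genus),
       seqs_per_species = as.integer(seqs_per_species),
       root_length = as.integer(root_length), d_genus = d_genus,
       d_species = d_species, d_within = d_within, pair = pair,
       fwd_start = as.integer(fwd_start),
       insert_length = as.integer(insert_length), order_name = order_name,
       genera_per_family = as.integer(genera_per_family),
       seed = as.integer(seed))
}

# Sample a concrete ACGT resolution of an IUPAC string.
.resolve_iupac <- function(seq) {
  mask <- .seq_mask(seq)
  paste(vapply(mask, function(m) {
    b <- c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

# Does `chars` contain a frame-0 stop codon (whole-sequence frame)?
.has_frame0_stop <- function(chars) {
  n <- length(chars)
  starts <- seq.int(1L, n - n %% 3L - 2L, by = 3L)
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  any(codons %in% .MITO_STOPS)
}

# Mutate eligible positions of a coding sequence at an expected per-site
# rate, with 3:1 bias toward third codon positions; substitutions creating
# a frame-0 stop or touching protected positions are suppressed.
.mutate_coding <- function(chars, rate, protected) {
  n <- length(chars)
  eligible <- setdiff(seq_len(n), protected)
  if (!length(eligible) || rate <= 0) return(chars)
  nmut <- stats::rbinom(1L, length(eligible), rate)
  if (nmut == 0L) return(chars)
  w <- ifelse(eligible %% 3L == 0L, 3, 1)
  pos <- sample(eligible, min(nmut, length(eligible)), prob = w)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    old <- chars[p]
    for (b in sample(setdiff(bases, old))) {
      chars[p] <- b
      cs <- p - (p - 1L) %% 3L
      codon <- paste0(chars[cs], chars[cs + 1L], chars[cs + 2L])
      if (!codon %in% .MITO_STOPS) break
      chars[p] <- old
    }
  }
  chars
}

#' Simulate a COI-like reference world
#'
#' Builds a random stop-free coding root, plants exact (IUPAC-resolved)
#' footprints of the primer pair, and derives genus, species and individual
#' sequences by hierarchical mutation with branch rates chosen so expected
#' pairwise divergences hit the targets (`d_genus` between genera,
#' `d_species` between congeners, `d_within` within species). Footprints
#' never mutate, frame-0 stops are never created, and third codon positions
#' mutate with 3:1 bias. Deterministic per seed.
#'
#' @param params [world_params()].
#' @return a `ref_library` with all records and taxonomy, plus extra
#'   elements `params`, `tree_newick` and `divergence` (realized mean
#'   divergences per level).
#' @export
simulate_reference_world <- function(params = world_params()) {
  withr::with_seed(params$seed, {
    p <- params
    mf <- nchar(p$pair$forward$sequence)
    mr <- nchar(p$pair$reverse$sequence)
    fwd0 <- p$fwd_start                      # 1-based start
    rev0 <- fwd0 + mf + p$insert_length      # 1-based start of rev footprint
    protected <- c(fwd0:(fwd0 + mf - 1L), rev0:(rev0 + mr - 1L))
    # root: stop-free codons, then plant stop-free footprint resolutions
    root <- NULL
    for (try in seq_len(200L)) {
      ncod <- ceiling(p$root_length / 3)
      chars <- strsplit(paste(sample(.NONSTOP_CODONS, ncod, replace = TRUE),
                              collapse = ""), "", fixed = TRUE)[[1]]
      chars <- chars[seq_len(p$root_length)]
      chars[fwd0:(fwd0 + mf - 1L)] <-
        strsplit(.resolve_iupac(p$pair$forward$sequence), "",
                 fixed = TRUE)[[1]]
      rc_rev <- reverse_complement(p$pair$reverse$sequence)
      chars[rev0:(rev0 + mr - 1L)] <-
        strsplit(.resolve_iupac(rc_rev), "", fixed = TRUE)[[1]]
      if (!.has_frame0_stop(chars)) { root <- chars; break }
    }
    if (is.null(root)) {
      stop("could not build a stop-free root with the planted footprints; ",
           "parameters may be infeasible")
    }
    r_g <- (p$d_genus - p$d_species) / 2
    r_s <- (p$d_species - p$d_within) / 2
    r_w <- p$d_within / 2
    ids <- character(0); seqs <- character(0)
    ord <- character(0); fam <- character(0)
    gen <- character(0); spp <- character(0)
    gclades <- character(p$n_genera)
    for (g in seq_len(p$n_genera)) {
      gname <- sprintf("Genus%02d", g)
      fname <- sprintf("Family%02d", ceiling(g / p$genera_per_family))
      ganc <- .mutate_coding(root, r_g, protected)
      sclades <- character(p$species_per_genus)
      for (s in seq_len(p$species_per_genus)) {
        sname <- sprintf("%s species%02d", gname, s)
        sanc <- .mutate_coding(ganc, r_s, protected)
        tips <- character(p$seqs_per_species)
        for (q in seq_len(p$seqs_per_species)) {
          id <- sprintf("G%02dS%02dI%02d", g, s, q)
          tip <- .mutate_coding(sanc, r_w, protected)
          ids <- c(ids, id); seqs <- c(seqs, paste(tip, collapse = ""))
          ord <- c(ord, p$order_name); fam <- c(fam, fname)
          gen <- c(gen, gname); spp <- c(spp, sname)
          tips[q] <- id
        }
        sclades[s] <- if (length(tips) > 1L)
          paste0("(", paste(tips, collapse = ","), ")") else tips
      }
      gclades[g] <- if (length(sclades) > 1L)
        paste0("(", paste(sclades, collapse = ","), ")") else sclades
    }
    newick <- paste0(if (length(gclades) > 1L)
      paste0("(", paste(gclades, collapse = ","), ")") else gclades, ";")
    records <- nuc_records(ids, seqs)
    records$marker <- "COI-5P"
    taxonomy <- data.frame(id = ids, order = ord, family = fam, genus = gen,
                           species = spp, stringsAsFactors = FALSE)
    lib <- ref_library(records, taxonomy)
    lib$params <- p
    lib$tree_newick <- newick
    lib$divergence <- .realized_divergence(records$seq, taxonomy)
    lib
  })
}

# Mean pairwise divergence within species / between congeners / between
# genera, on a bounded subsample of pairs.
.realized_divergence <- function(seqs, taxonomy, max_pairs = 2000L) {
  n <- length(seqs)
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) pairs <- pairs[, seq_len(max_pairs)]
  d <- numeric(ncol(pairs)); lvl <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d[k] <- 1 - seq_identity(seqs[i], seqs[j])
    lvl[k] <- if (taxonomy$species[i] == taxonomy$species[j]) "within_species"
      else if (taxonomy$genus[i] == taxonomy$genus[j]) "between_species"
      else "between_genus"
  }
  tapply(d, factor(lvl, levels = c("within_species", "between_species",
                                   "between_genus")), mean)
}

#' Pool specification for simulated reads
#'
#' @param proportions named numeric vector, species -> template proportion
#'   (must sum to 1).
#' @param n_pairs total read pairs.
#' @param read_length read length of each mate.
#' @param quality constant per-base Phred quality; the substitution error
#'   rate is `10^(-quality/10)` (no indels).
#' @param seed RNG seed.
#' @return a `pool_spec` list.
#' @export
pool_spec <- function(proportions, n_pairs = 20000L, read_length = 150L,
                      quality = 33L, seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, n_pairs >= 1L,
            !is.null(names(proportions)))
  list(proportions = proportions, n_pairs = as.integer(n_pairs),
       read_length = as.integer(read_length), quality = as.integer(quality),
       seed = as.integer(seed))
}

#' Simulate pooled paired-end amplicon reads from a reference world
#'
#' Templates are the planted pair's amplicons (product including both
#' footprints) of each pool species' first record, with the universal tails
#' prepended on each strand. Read pairs are drawn multinomially by
#' proportion; each base is substituted with probability `10^(-Q/10)`.
#' Byte-identical per seed.
#'
#' @param world a world from [simulate_reference_world()].
#' @param spec a [pool_spec()]; names of `spec$proportions` must be species
#'   present in the world.
#' @param tails universal tails (default [universal_tails()]).
#' @return list with `pairs` (a `read_pairs` data frame), `truth` (data
#'   frame id, species) and `templates`.
#' @export
simulate_pooled_reads <- function(world, spec, tails = universal_tails()) {
  withr::with_seed(spec$seed, {
    sp <- names(spec$proportions)
    missing <- setdiff(sp, world$taxonomy$species)
    if (length(missing)) {
      stop("species not in world: ", paste(missing, collapse = ", "))
    }
    rec_id <- vapply(sp, function(s) {
      world$taxonomy$id[world$taxonomy$species == s][1L]
    }, character(1))
    recs <- world$records[match(rec_id, world$records$id), , drop = FALSE]
    hits <- insilico_pcr(world$params$pair, recs)
    if (nrow(hits) < length(sp)) {
      stop("species without amplicon: ",
           paste(setdiff(rec_id, hits$ref_id), collapse = ", "))
    }
    product <- hits$product[match(rec_id, hits$ref_id)]
    tpl_f <- paste0(.norm_seq(tails[[1]]), product)
    tpl_r <- paste0(.norm_seq(tails[[2]]), reverse_complement(product))
    counts <- as.vector(stats::rmultinom(1L, spec$n_pairs,
                                         spec$proportions))
    src <- rep(seq_along(sp), counts)
    src <- src[sample.int(length(src))]
    rl <- spec$read_length
    err <- 10^(-spec$quality / 10)
    make_reads <- function(tpl) {
      full <- vapply(tpl, function(t) {
        if (nchar(t) >= rl) substr(t, 1L, rl)
        else paste0(t, paste(rep("A", rl - nchar(t)), collapse = ""))
      }, character(1), USE.NAMES = FALSE)
      M <- matrix(unlist(strsplit(full[src], "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(src), byrow = TRUE)
      hit <- which(stats::runif(length(M)) < err)
      if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        M[hit] <- vapply(M[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
      do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
    }
    r1 <- make_reads(tpl_f)
    r2 <- make_reads(tpl_r)
    qual <- paste(rep(intToUtf8(spec$quality + 33L), rl), collapse = "")
    ids <- sprintf("pool_%06d", seq_along(src))
    pairs <- read_pairs(nuc_records(ids, r1, qual = qual),
                        nuc_records(ids, r2, qual = qual))
    list(pairs = pairs,
         truth = data.frame(id = ids, species = sp[src],
                            stringsAsFactors = FALSE),
         templates = data.frame(species = sp, product = product,
                                stringsAsFactors = FALSE))
  })
}

#' Write a simulated pool to paired FASTQ plus truth TSV
#'
#' @param pool output of [simulate_pooled_reads()].
#' @param dir output directory.
#' @param stem file stem.
#' @return named vector of written paths, invisibly.
#' @export
write_pool <- function(pool, dir, stem = "pool") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(r1 = file.path(dir, paste0(stem, "_R1.fastq")),
             r2 = file.path(dir, paste0(stem, "_R2.fastq")),
             truth = file.path(dir, paste0(stem, "_truth.tsv")))
  p <- pool$pairs
  write_fastq(nuc_records(p$id, p$seq1, qual = p$qual1), paths[["r1"]])
  write_fastq(nuc_records(p$id, p$seq2, qual = p$qual2), paths[["r2"]])
  utils::write.table(pool$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
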