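# Degenerate primer representation, weighted-mismatch site scoring,
# in-silico PCR, de novo design and per-taxon coverage reports.

#' Create a degenerate primer
#'
#' @param name primer name.
#' @param sequence IUPAC string, 5'->3' in the primer's own sense.
#' @param orientation `"forward"` or `"reverse"`.
#' @param degeneracy_cap maximum allowed degeneracy (product of per-position
#'   base-set sizes).
#' @param min_length minimum primer length.
#' @return a `degenerate_primer` list.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse"),
                              degeneracy_cap = 512, min_length = 15L) {
  orientation <- match.arg(orientation)
  sequence <- .norm_seq(sequence)
  .check_alphabet(sequence, name)
  if (nchar(sequence) < min_length) {
    stop("primer '", name, "' shorter than ", min_length, " nt")
  }
  dg <- degeneracy(sequence)
  if (dg > degeneracy_cap) {
    stop("primer '", name, "' degeneracy ", dg, " exceeds cap ", degeneracy_cap)
  }
  structure(list(name = name, sequence = sequence, orientation = orientation,
                 degeneracy = dg),
            class = "degenerate_primer")
}

#' Weighted-mismatch scoring parameters
#'
#' Mismatches are weighted by position within the primer: `w_non3` outside
#' the 3' window, `w_3` inside the last `three_prime_window` bases, and
#' `w_terminal` for the 3'-terminal base. A site is a hit when its weighted
#' score is at most `hit_threshold`. Matching is gapless.
#'
#' @param three_prime_window length of the 3' window in nt.
#' @param w_non3,w_3,w_terminal mismatch weights (>= 0).
#' @param hit_threshold maximum weighted score for a hit.
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(three_prime_window = 5L, w_non3 = 0.4, w_3 = 1.0,
                           w_terminal = 3.0, hit_threshold = 1.0) {
  stopifnot(w_non3 >= 0, w_3 >= 0, w_terminal >= 0, hit_threshold >= 0,
            three_prime_window >= 1L)
  list(three_prime_window = as.integer(three_prime_window), w_non3 = w_non3,
       w_3 = w_3, w_terminal = w_terminal, hit_threshold = hit_threshold)
}

# Per-position penalty vector in the primer's own 5'->3' sense.
.penalty_vector <- function(m, params) {
  p <- rep(params$w_non3, m)
  tw <- min(params$three_prime_window, m)
  p[(m - tw + 1L):m] <- params$w_3
  p[m] <- params$w_terminal
  p
}

# Primer code mask + penalties oriented for comparison against the plus
# strand: for reverse primers the footprint on the plus strand is the
# reverse complement, so both vectors are flipped.
.plus_strand_view <- function(primer, params) {
  m <- nchar(primer$sequence)
  pen <- .penalty_vector(m, params)
  if (primer$orientation == "reverse") {
    list(mask = .seq_mask(reverse_complement(primer$sequence)),
         penalty = rev(pen))
  } else {
    list(mask = .seq_mask(primer$sequence), penalty = pen)
  }
}

.site_counts <- function(mism, primer_len, params, orientation) {
  # mism: logical vector in plus-strand order; convert to primer sense
  if (orientation == "reverse") mism <- rev(mism)
  tw <- min(params$three_prime_window, primer_len)
  in3 <- seq_len(primer_len) > primer_len - tw
  list(mismatches_non3 = sum(mism & !in3),
       mismatches_3 = sum(mism & in3),
       terminal_mismatch = mism[primer_len])
}

#' Score a primer against a same-length sequence window
#'
#' The window is given on the plus strand; reverse primers are compared as
#' their reverse complement. The weighted score is
#' `w_non3 * mm_non3 + w_3 * (mm_3 - terminal) + w_terminal * terminal`,
#' where `mm_3` counts mismatches in the 3' window (terminal included).
#'
#' @param primer a [degenerate_primer()].
#' @param window_sequence plus-strand window, same length as the primer.
#' @param params [scoring_params()].
#' @return a `site_match` list (`weighted_score`, mismatch counts,
#'   `terminal_mismatch`).
#' @export
score_site <- function(primer, window_sequence, params = scoring_params()) {
  window_sequence <- .norm_seq(window_sequence)
  m <- nchar(primer$sequence)
  if (nchar(window_sequence) != m) {
    stop("window length ", nchar(window_sequence),
         " differs from primer length ", m)
  }
  v <- .plus_strand_view(primer, params)
  mism <- bitwAnd(.seq_mask(window_sequence), v$mask) == 0L
  cnt <- .site_counts(mism, m, params, primer$orientation)
  score <- sum(v$penalty[mism])
  structure(c(list(primer = primer$name, strand = if (primer$orientation ==
                "reverse") "-" else "+",
                weighted_score = score), cnt), class = "site_match")
}

# All-offset weighted scores of a primer against one plus-strand sequence.
# Returns numeric vector, element o = score at 0-based start o-1.
.scan_scores <- function(primer_mask, penalty, seq_mask_vec) {
  m <- length(primer_mask)
  n <- length(seq_mask_vec)
  if (n < m) return(numeric(0))
  noff <- n - m + 1L
  idx <- rep(seq_len(m), noff) + rep(0:(noff - 1L), each = m)
  mism <- bitwAnd(seq_mask_vec[idx], primer_mask) == 0L
  colSums(matrix(penalty * mism, nrow = m))
}

#' Find the best-scoring binding site of a primer on a record
#'
#' Slides the (gapless) primer over the plus strand (as reverse complement
#' for reverse primers) and returns the minimum-score position; ties go to
#' the smallest start. A hit exists iff the score is at most
#' `params$hit_threshold`.
#'
#' @param primer a [degenerate_primer()].
#' @param record a single-row [nuc_records()] data frame or an IUPAC string.
#' @param params [scoring_params()].
#' @return a `site_match` list with `ref_id`, 0-based plus-strand `start`,
#'   `end` (exclusive), `strand`, `weighted_score`, mismatch counts and
#'   `hit`; or `NULL` if the record is shorter than the primer.
#' @export
scan_best_site <- function(primer, record, params = scoring_params()) {
  if (is.character(record)) record <- nuc_records("query", record)
  s <- record$seq[1L]
  m <- nchar(primer$sequence)
  if (nchar(s) < m) return(NULL)
  v <- .plus_strand_view(primer, params)
  smask <- .seq_mask(s)
  scores <- .scan_scores(v$mask, v$penalty, smask)
  o <- which.min(scores)
  mism <- bitwAnd(smask[o:(o + m - 1L)], v$mask) == 0L
  cnt <- .site_counts(mism, m, params, primer$orientation)
  structure(c(list(ref_id = record$id[1L], primer = primer$name,
                   start = o - 1L, end = o - 1L + m,
                   strand = if (primer$orientation == "reverse") "-" else "+",
                   weighted_score = scores[o],
                   hit = scores[o] <= params$hit_threshold), cnt),
            class = "site_match")
}

#' In-silico PCR: extract amplicons for a primer pair
#'
#' For each record, candidate sites of both primers (weighted score at most
#' `hit_threshold`) are enumerated and the compatible pair (forward
#' footprint strictly upstream of the reverse footprint) with the smallest
#' total score is kept, ties resolved to the smallest start positions. The
#' product spans the first base of the forward footprint through the last
#' base of the reverse footprint inclusive; the insert is the product minus
#' both footprints.
#'
#' @param pair list with elements `forward` and `reverse`, each a
#'   [degenerate_primer()].
#' @param records a [nuc_records()] data frame.
#' @param params [scoring_params()].
#' @return an `amplicon_hits` data frame (one row per amplified record) with
#'   columns ref_id, fwd_start, fwd_score, rev_start, rev_score,
#'   product_length, product, insert; records without an amplicon are listed
#'   in the `"log"` attribute with a reason.
#' @export
insilico_pcr <- function(pair, records, params = scoring_params()) {
  stopifnot(pair$forward$orientation == "forward",
            pair$reverse$orientation == "reverse")
  vf <- .plus_strand_view(pair$forward, params)
  vr <- .plus_strand_view(pair$reverse, params)
  mf <- length(vf$mask); mr <- length(vr$mask)
  rows <- vector("list", nrow(records))
  log <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    smask <- .seq_mask(records$seq[i])
    fs <- .scan_scores(vf$mask, vf$penalty, smask)
    rs <- .scan_scores(vr$mask, vr$penalty, smask)
    fo <- which(fs <= params$hit_threshold)
    ro <- which(rs <= params$hit_threshold)
    if (!length(fo) || !length(ro)) {
      log[[i]] <- data.frame(id = records$id[i],
                             reason = if (!length(fo)) "no_forward_site"
                                      else "no_reverse_site")
      next
    }
    # best compatible pair: forward footprint strictly upstream of reverse
    best <- NULL
    for (f in fo) {
      ok <- ro[ro >= f + mf]
      if (!length(ok)) next
      r <- ok[which.min(rs[ok])]
      tot <- fs[f] + rs[r]
      if (is.null(best) || tot < best$tot) best <- list(f = f, r = r, tot = tot)
    }
    if (is.null(best)) {
      log[[i]] <- data.frame(id = records$id[i], reason = "overlapping_footprints")
      next
    }
    f <- best$f; r <- best$r
    prod_start <- f
    prod_end <- r + mr - 1L
    product <- substr(records$seq[i], prod_start, prod_end)
    insert <- substr(records$seq[i], prod_start + mf, prod_end - mr)
    rows[[i]] <- data.frame(
      ref_id = records$id[i], fwd_start = f - 1L, fwd_score = fs[f],
      rev_start = r - 1L, rev_score = rs[r],
      product_length = nchar(product), product = product, insert = insert,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(ref_id = character(), fwd_start = integer(),
                       fwd_score = numeric(), rev_start = integer(),
                       rev_score = numeric(), product_length = integer(),
                       product = character(), insert = character(),
                       stringsAsFactors = FALSE)
  }
  attr(hits, "log") <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  class(hits) <- c("amplicon_hits", "data.frame")
  hits
}

#' Per-taxon amplification coverage
#'
#' @param hits an `amplicon_hits` data frame from [insilico_pcr()].
#' @param taxonomy taxonomy data frame (id + ranks); records with no lineage
#'   at `rank` are pooled under `"unassigned"`.
#' @param rank taxonomic rank to aggregate at.
#' @return data frame (rank, taxon, n_total, n_amplified, coverage) with the
#'   overall amplified fraction in attribute `"overall"`.
#' @export
taxon_coverage <- function(hits, taxonomy, rank = "genus") {
  stopifnot(rank %in% c("order", "family", "genus", "species"))
  taxon <- taxonomy[[rank]]
  taxon[is.na(taxon)] <- "unassigned"
  amp <- taxonomy$id %in% hits$ref_id
  tot <- tapply(rep(1L, length(taxon)), taxon, sum)
  namp <- tapply(as.integer(amp), taxon, sum)
  out <- data.frame(rank = rank, taxon = names(tot),
                    n_total = as.integer(tot), n_amplified = as.integer(namp),
                    coverage = as.numeric(namp / tot),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "overall") <- mean(amp)
  out
}

#' Design parameters for de novo degenerate primer search
#'
#' @param primer_length candidate primer length in nt.
#' @param seed_k exact word size used to locate conserved anchors.
#' @param seed_fraction minimum fraction of targets containing a seed word.
#' @param band maximum deviation (nt) of a target's anchor position from the
#'   median anchor before the target is left out of the profile.
#' @param base_freq_min minimum per-position base frequency for inclusion in
#'   the IUPAC code.
#' @param degeneracy_cap maximum candidate degeneracy.
#' @param max_candidates cap on the number of ranked candidates returned.
#' @param scoring [scoring_params()] used for coverage evaluation.
#' @return a `design_params` list.
#' @export
design_params <- function(primer_length = 26L, seed_k = 5L,
                          seed_fraction = 0.6, band = 10L,
                          base_freq_min = 0.05, degeneracy_cap = 512,
                          max_candidates = 10L,
                          scoring = scoring_params()) {
  list(primer_length = as.integer(primer_length), seed_k = as.integer(seed_k),
       seed_fraction = seed_fraction, band = as.integer(band),
       base_freq_min = base_freq_min, degeneracy_cap = degeneracy_cap,
       max_candidates = as.integer(max_candidates), scoring = scoring)
}

# IUPAC consensus of a character matrix column under a frequency floor.
.consensus_code <- function(col, freq_min) {
  tab <- table(factor(col, levels = c("A", "C", "G", "T")))
  keep <- tab / sum(tab) >= freq_min
  if (!any(keep)) return(NA_character_)
  mask <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[keep])
  .MASK_LETTER[mask]
}

#' De novo design of degenerate primers from conserved regions
#'
#' Anchors targets on their most widely shared exact `seed_k`-mer, builds
#' per-position base-frequency profiles for every primer-length window
#' containing the seed, emits the IUPAC consensus of each window (bases with
#' frequency >= `base_freq_min`), and scores candidates against the target
#' and exclusion sets. Candidates are ranked by target coverage (descending),
#' exclusion coverage (ascending) and degeneracy (ascending).
#'
#' @param target_records,exclusion_records [nuc_records()] data frames; the
#'   exclusion set may be empty or `NULL`.
#' @param params [design_params()].
#' @return data frame of ranked candidates (name, sequence, orientation,
#'   target_coverage, exclusion_coverage, mean_score, degeneracy). Empty
#'   with attribute `"diagnostic"` when no conserved seed exists.
#' @export
design_primers <- function(target_records, exclusion_records = NULL,
                           params = design_params()) {
  empty <- data.frame(name = character(), sequence = character(),
                      orientation = character(), target_coverage = numeric(),
                      exclusion_coverage = numeric(), mean_score = numeric(),
                      degeneracy = numeric(), stringsAsFactors = FALSE)
  n <- nrow(target_records)
  if (n == 0L) { attr(empty, "diagnostic") <- "no targets"; return(empty) }
  k <- params$seed_k
  L <- params$primer_length
  words <- lapply(target_records$seq, .kmers, k = k)
  tab <- sort(table(unlist(words)), decreasing = TRUE)
  shared <- tab[tab >= params$seed_fraction * n]
  if (!length(shared)) {
    attr(empty, "diagnostic") <- "no conserved seed found"
    return(empty)
  }
  # best seed: highest prevalence, ties lexicographic
  top <- names(shared)[shared == max(shared)]
  seed <- sort(top)[1L]
  anchor <- vapply(target_records$seq,
                   function(s) regexpr(seed, s, fixed = TRUE)[[1]], numeric(1))
  has <- anchor > 0
  a_med <- stats::median(anchor[has])
  keep <- has & abs(anchor - a_med) <= params$band
  seqs <- target_records$seq[keep]
  anchors <- anchor[keep]
  cands <- character(0)
  for (d in -(L - k):0) {
    starts <- anchors + d
    ok <- starts >= 1 & starts + L - 1 <= nchar(seqs)
    if (sum(ok) < params$seed_fraction * n) next
    win <- substr(seqs[ok], starts[ok], starts[ok] + L - 1L)
    if (any(grepl("[^ACGT]", win))) next
    mat <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                  nrow = sum(ok), byrow = TRUE)
    code <- apply(mat, 2L, .consensus_code, freq_min = params$base_freq_min)
    if (anyNA(code)) next
    cand <- paste(code, collapse = "")
    if (degeneracy(cand) <= params$degeneracy_cap) cands <- c(cands, cand)
  }
  cands <- unique(cands)
  if (!length(cands)) {
    attr(empty, "diagnostic") <- "no candidate under degeneracy cap"
    return(empty)
  }
  score_set <- function(cand, recs) {
    if (is.null(recs) || nrow(recs) == 0L) return(c(0, NA_real_))
    pr <- degenerate_primer("cand", cand, "forward",
                            degeneracy_cap = params$degeneracy_cap)
    sc <- vapply(seq_len(nrow(recs)), function(i) {
      s <- scan_best_site(pr, recs[i, , drop = FALSE], params$scoring)
      if (is.null(s)) Inf else s$weighted_score
    }, numeric(1))
    c(mean(sc <= params$scoring$hit_threshold), mean(sc[is.finite(sc)]))
  }
  tgt <- t(vapply(cands, score_set, numeric(2), recs = target_records))
  exc <- t(vapply(cands, score_set, numeric(2), recs = exclusion_records))
  out <- data.frame(name = paste0("cand_", seq_along(cands)),
                    sequence = cands, orientation = "forward",
                    target_coverage = tgt[, 1L],
                    exclusion_coverage = exc[, 1L],
                    mean_score = tgt[, 2L],
                    degeneracy = vapply(cands, degeneracy, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$target_coverage, out$exclusion_coverage,
                   out$degeneracy, out$sequence), , drop = FALSE]
  out <- utils::head(out, params$max_candidates)
  out$name <- paste0("cand_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Bundled mini-barcode primer set
#'
#' The seven SFF COI mini-barcode primers plus the BEGLCOI barcoding pair,
#' as a data frame (name, sequence, orientation). `primer_pair()` fetches a
#' named forward/reverse pair from it.
#'
#' @return data frame of primers.
#' @export
sff_primers <- function() {
  data.frame(
    name = c("SFF_145f", "SFF_210f", "SFF_348f", "SFF_351f",
             "SFF_348r", "SFF_351r", "SFF_492r", "BEGLCOIf", "BEGLCOIr"),
    sequence = c("GTHACHGCYCAYGCHTTYGTAATAAT",
                 "GGAAAYTGRYTARTHCCHYTRATAATTGG",
                 "CMGTHTAYCCYCCYYTAGCAGG",
                 "CMGTHTAYCCHCCHYTAGCAGGAAA",
                 "GCATGDGCDAGRTTYCCNGC",
                 "CTCCWGCRTGDGCWAGRTTTCC",
                 "ACDGATCAKACRAAYARKGGTG",
                 "GGYGCYTGAGCHGGWATAGT",
                 "ARRATDGGRTCYCCYCCTCC"),
    orientation = c("forward", "forward", "forward", "forward",
                    "reverse", "reverse", "reverse", "forward", "reverse"),
    stringsAsFactors = FALSE)
}

#' Fetch a forward/reverse primer pair by name
#'
#' @param forward,reverse primer names present in `primers`.
#' @param primers a primer definition data frame (default [sff_primers()]).
#' @param degeneracy_cap cap passed to [degenerate_primer()]; the bundled
#'   set includes one primer of degeneracy 576, hence the raised default.
#' @return list with [degenerate_primer()] elements `forward` and `reverse`.
#' @export
primer_pair <- function(forward = "SFF_145f", reverse = "SFF_351r",
                        primers = sff_primers(), degeneracy_cap = 1024) {
  pick <- function(nm, want) {
    i <- match(nm, primers$name)
    if (is.na(i)) stop("unknown primer: ", nm)
    if (primers$orientation[i] != want) {
      stop("primer ", nm, " is not a ", want, " primer")
    }
    degenerate_primer(nm, primers$sequence[i], want,
                      degeneracy_cap = degeneracy_cap)
  }
  list(forward = pick(forward, "forward"), reverse = pick(reverse, "reverse"))
}

#' Read primer definitions from TSV (name, sequence, orientation)
#' @param path TSV path with header.
#' @return data frame of primers.
#' @export
read_primers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence", "orientation") %in% names(df)))
  df
}
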