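# Pooled-sample amplicon read processing: universal-tail/primer stripping,
# pair merging with quality consensus, screening, dereplication, two-parent
# chimera flagging and per-species sample profiling.

#' Default universal tails
#'
#' The fixed 5' extensions added to the target primers for indexed pooled
#' sequencing (UT1 on the forward primer, UT2 on the reverse primer).
#' @return named character vector of length 2.
#' @export
universal_tails <- function() {
  c(UT1 = "ACCCAACTGAATGGAGC", UT2 = "ACGCACTTGACTTGTCTTC")
}

#' Assemble paired reads
#'
#' @param fwd,rev [nuc_records()] data frames of forward and reverse mates
#'   (same ids, same order, qualities present).
#' @return a `read_pairs` data frame (id, seq1, qual1, seq2, qual2).
#' @export
read_pairs <- function(fwd, rev) {
  if (nrow(fwd) != nrow(rev) || !all(fwd$id == rev$id)) {
    stop("forward and reverse mates must pair by id and order")
  }
  if (anyNA(fwd$qual) || anyNA(rev$qual)) stop("paired reads need qualities")
  df <- data.frame(id = fwd$id, seq1 = fwd$seq, qual1 = fwd$qual,
                   seq2 = rev$seq, qual2 = rev$qual, stringsAsFactors = FALSE)
  class(df) <- c("read_pairs", "data.frame")
  df
}

#' Read a pair of FASTQ files into `read_pairs`
#' @param path_fwd,path_rev FASTQ paths for the two mates.
#' @return a `read_pairs` data frame.
#' @export
read_paired_fastq <- function(path_fwd, path_rev) {
  read_pairs(read_fastq(path_fwd), read_fastq(path_rev))
}

#' Primer/tail stripping parameters
#' @param search_window leading offsets (nt) searched for the tail+primer.
#' @param require_primer reject mates whose tail+primer is not found?
#' @param scoring [scoring_params()] used for the match.
#' @return a `strip_params` list.
#' @export
strip_params <- function(search_window = 3L, require_primer = TRUE,
                         scoring = scoring_params()) {
  list(search_window = as.integer(search_window),
       require_primer = isTRUE(require_primer), scoring = scoring)
}

# Best leading match of adapter (IUPAC) within the first offsets of reads.
# Returns list(offset = best 0-based offset or NA, score).
.lead_match <- function(seqs, adapter, params) {
  la <- nchar(adapter)
  amask <- .seq_mask(adapter)
  pen <- .penalty_vector(la, params$scoring)
  best_off <- rep(NA_integer_, length(seqs))
  best_sc <- rep(Inf, length(seqs))
  for (o in 0:params$search_window) {
    ok <- nchar(seqs) >= o + la
    if (!any(ok)) next
    win <- substr(seqs[ok], o + 1L, o + la)
    M <- .seq_mask_matrix(win)
    mism <- matrix(bitwAnd(M, matrix(amask, nrow(M), la, byrow = TRUE)) == 0L,
                   nrow = nrow(M))
    sc <- as.numeric(mism %*% pen)
    cur <- rep(Inf, length(seqs)); cur[ok] <- sc
    take <- cur < best_sc
    best_sc[take] <- cur[take]
    best_off[take] <- o
  }
  list(offset = best_off, score = best_sc)
}

#' Strip universal tails and primers from read pairs
#'
#' Looks for `tail + primer` at the 5' end of each mate (forward mate: UT1 +
#' forward primer; reverse mate: UT2 + reverse primer, both in read sense)
#' within the first `search_window` offsets, using the weighted-mismatch
#' score. When found at score <= `hit_threshold` the leading bases through
#' the primer are removed; otherwise the pair is rejected when
#' `require_primer` is set.
#'
#' @param pairs a `read_pairs` data frame.
#' @param pair primer pair ([primer_pair()]).
#' @param tails character vector of the two universal tails
#'   (default [universal_tails()]).
#' @param params [strip_params()].
#' @return list with `pairs` (trimmed `read_pairs`) and `rejects` (data
#'   frame id, reason).
#' @export
strip_primers_tails <- function(pairs, pair, tails = universal_tails(),
                                params = strip_params()) {
  ad1 <- paste0(.norm_seq(tails[[1]]), pair$forward$sequence)
  ad2 <- paste0(.norm_seq(tails[[2]]), pair$reverse$sequence)
  m1 <- .lead_match(pairs$seq1, ad1, params)
  m2 <- .lead_match(pairs$seq2, ad2, params)
  thr <- params$scoring$hit_threshold
  ok1 <- !is.na(m1$offset) & m1$score <= thr
  ok2 <- !is.na(m2$offset) & m2$score <= thr
  keep <- if (params$require_primer) ok1 & ok2 else rep(TRUE, nrow(pairs))
  cut1 <- ifelse(ok1, m1$offset + nchar(ad1), 0L)
  cut2 <- ifelse(ok2, m2$offset + nchar(ad2), 0L)
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- substr(out$seq1, cut1[keep] + 1L, nchar(out$seq1))
  out$qual1 <- substr(out$qual1, cut1[keep] + 1L, nchar(out$qual1))
  out$seq2 <- substr(out$seq2, cut2[keep] + 1L, nchar(out$seq2))
  out$qual2 <- substr(out$qual2, cut2[keep] + 1L, nchar(out$qual2))
  rejects <- data.frame(
    id = pairs$id[!keep],
    reason = ifelse(!ok1[!keep], "no_forward_primer", "no_reverse_primer"),
    stringsAsFactors = FALSE)
  list(pairs = out, rejects = rejects)
}

#' Pair-merging parameters
#' @param min_overlap minimum overlap length (nt).
#' @param max_mismatch_rate maximum fraction of mismatching overlap columns.
#' @return a `merge_params` list.
#' @export
merge_params <- function(min_overlap = 20L, max_mismatch_rate = 0.10) {
  list(min_overlap = as.integer(min_overlap),
       max_mismatch_rate = max_mismatch_rate)
}

# Consensus of two aligned bases with qualities.
# Agreement: base kept, Q = min(Q1+Q2, 45). Conflict: higher-Q base kept,
# Q = |Q1-Q2|.
.consensus <- function(b1, q1, b2, q2) {
  agree <- b1 == b2
  base <- ifelse(agree, b1, ifelse(q1 >= q2, b1, b2))
  qual <- ifelse(agree, pmin(q1 + q2, 45L), abs(q1 - q2))
  list(base = base, qual = qual)
}

#' Merge one read pair into a contig
#'
#' The reverse mate is reverse-complemented and slid over the forward mate;
#' the overlap maximizing matching columns (ties: fewer mismatches, then
#' longer overlap) is kept if it is at least `min_overlap` long with a
#' mismatch fraction at most `max_mismatch_rate`. Overlap disagreements
#' resolve to the higher-quality base.
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual mate sequences and Phred+33
#'   quality strings (reverse mate in its own read sense).
#' @param params [merge_params()].
#' @return list(seq, qual, overlap_length, overlap_mismatches) or `NULL` on
#'   failure.
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                       params = merge_params()) {
  rc <- reverse_complement(rev_seq)
  rq <- rev(phred_ints(rev_qual))
  f <- strsplit(fwd_seq, "", fixed = TRUE)[[1]]
  fq <- phred_ints(fwd_qual)
  r <- strsplit(rc, "", fixed = TRUE)[[1]]
  l1 <- length(f); l2 <- length(r)
  if (min(l1, l2) < params$min_overlap) return(NULL)
  best <- NULL
  for (ov in params$min_overlap:min(l1, l2)) {
    a <- f[(l1 - ov + 1L):l1]
    b <- r[1:ov]
    mm <- sum(a != b)
    if (is.null(best) || (ov - mm) > (best$ov - best$mm) ||
        ((ov - mm) == (best$ov - best$mm) && mm < best$mm)) {
      best <- list(ov = ov, mm = mm)
    }
  }
  if (is.null(best) || best$mm / best$ov > params$max_mismatch_rate) {
    return(NULL)
  }
  ov <- best$ov
  cons <- .consensus(f[(l1 - ov + 1L):l1], fq[(l1 - ov + 1L):l1],
                     r[1:ov], rq[1:ov])
  seq <- paste(c(f[seq_len(l1 - ov)], cons$base, r[-seq_len(ov)]),
               collapse = "")
  qual <- phred_chars(c(fq[seq_len(l1 - ov)], cons$qual, rq[-seq_len(ov)]))
  list(seq = seq, qual = qual, overlap_length = ov,
       overlap_mismatches = best$mm)
}

#' Merge all pairs in a `read_pairs` set
#'
#' Vectorized over groups of identical mate lengths; per-read results match
#' [merge_pair()].
#'
#' @param pairs a `read_pairs` data frame (already primer-stripped).
#' @param params [merge_params()].
#' @return list with `merged` (data frame id, seq, qual, overlap_length,
#'   overlap_mismatches) and `failures` (data frame id, reason).
#' @export
merge_pairs <- function(pairs, params = merge_params()) {
  n <- nrow(pairs)
  res_seq <- character(n); res_qual <- character(n)
  res_ov <- integer(n); res_mm <- integer(n)
  okv <- logical(n)
  grp <- paste(nchar(pairs$seq1), nchar(pairs$seq2))
  for (g in unique(grp)) {
    gi <- which(grp == g)
    l1 <- nchar(pairs$seq1[gi[1]]); l2 <- nchar(pairs$seq2[gi[1]])
    if (min(l1, l2) < params$min_overlap) next
    Fm <- matrix(unlist(strsplit(pairs$seq1[gi], "", fixed = TRUE),
                        use.names = FALSE), nrow = length(gi), byrow = TRUE)
    Rc <- matrix(unlist(strsplit(reverse_complement(pairs$seq2[gi]), "",
                                 fixed = TRUE),
                        use.names = FALSE), nrow = length(gi), byrow = TRUE)
    FQ <- matrix(utf8ToInt(paste(pairs$qual1[gi], collapse = "")) - 33L,
                 nrow = length(gi), byrow = TRUE)
    RQ <- matrix(utf8ToInt(paste(pairs$qual2[gi], collapse = "")) - 33L,
                 nrow = length(gi), byrow = TRUE)[, l2:1, drop = FALSE]
    ovs <- params$min_overlap:min(l1, l2)
    mmM <- matrix(0L, nrow = length(gi), ncol = length(ovs))
    for (j in seq_along(ovs)) {
      ov <- ovs[j]
      mmM[, j] <- rowSums(Fm[, (l1 - ov + 1L):l1, drop = FALSE] !=
                            Rc[, 1:ov, drop = FALSE])
    }
    scoreM <- matrix(ovs, nrow = length(gi), ncol = length(ovs),
                     byrow = TRUE) - mmM
    # maximize matches; break ties toward fewer mismatches (equal matches
    # and mismatches force equal overlap, so no further tie-break needed)
    bestj <- apply(scoreM - mmM * 1e-4, 1L, which.max)
    ov <- ovs[bestj]
    mm <- mmM[cbind(seq_along(gi), bestj)]
    ok <- mm / ov <= params$max_mismatch_rate
    for (u in unique(ov[ok])) {
      sel <- which(ok & ov == u)
      rows <- gi[sel]
      a <- Fm[sel, (l1 - u + 1L):l1, drop = FALSE]
      b <- Rc[sel, 1:u, drop = FALSE]
      qa <- FQ[sel, (l1 - u + 1L):l1, drop = FALSE]
      qb <- RQ[sel, 1:u, drop = FALSE]
      agree <- a == b
      consb <- ifelse(agree, a, ifelse(qa >= qb, a, b))
      consq <- ifelse(agree, pmin(qa + qb, 45L), abs(qa - qb))
      left <- Fm[sel, seq_len(l1 - u), drop = FALSE]
      right <- Rc[sel, -seq_len(u), drop = FALSE]
      seqM <- cbind(left, consb, right)
      qualM <- cbind(FQ[sel, seq_len(l1 - u), drop = FALSE], consq,
                     RQ[sel, -seq_len(u), drop = FALSE])
      res_seq[rows] <- do.call(paste0, as.data.frame(seqM,
                                                     stringsAsFactors = FALSE))
      res_qual[rows] <- apply(qualM, 1L, phred_chars)
      res_ov[rows] <- u
      res_mm[rows] <- mmM[cbind(sel, bestj[sel])]
      okv[rows] <- TRUE
    }
  }
  merged <- data.frame(id = pairs$id[okv], seq = res_seq[okv],
                       qual = res_qual[okv], overlap_length = res_ov[okv],
                       overlap_mismatches = res_mm[okv],
                       stringsAsFactors = FALSE)
  failures <- data.frame(id = pairs$id[!okv],
                         reason = rep("merge_failed", sum(!okv)),
                         stringsAsFactors = FALSE)
  list(merged = merged, failures = failures)
}

#' Screening / dereplication parameters
#' @param l_expected expected merged length (nt), e.g. the insert length of
#'   the active primer pair.
#' @param delta allowed deviation from `l_expected` (nt).
#' @return a `screen_params` list.
#' @export
screen_params <- function(l_expected, delta = 10L) {
  list(l_expected = as.integer(l_expected), delta = as.integer(delta))
}

#' Screen merged reads and collapse exact duplicates
#'
#' Removes reads containing ambiguous characters or of length outside
#' `l_expected +/- delta`, then collapses identical sequences into unique
#' sequences with abundances.
#'
#' @param merged data frame (id, seq, ...) from [merge_pairs()].
#' @param params [screen_params()].
#' @return list with `uniques` (data frame seq, abundance, rep_id; sorted by
#'   abundance descending) and `rejects` (data frame id, reason).
#' @export
screen_dereplicate <- function(merged, params) {
  ambig <- grepl("[^ACGT]", merged$seq)
  len <- nchar(merged$seq)
  badlen <- len < params$l_expected - params$delta |
    len > params$l_expected + params$delta
  reason <- ifelse(ambig, "ambiguous",
                   ifelse(badlen, "length", NA_character_))
  kept <- merged[is.na(reason), , drop = FALSE]
  f <- factor(kept$seq, levels = unique(kept$seq))
  uniques <- data.frame(seq = levels(f),
                        abundance = as.integer(table(f)),
                        rep_id = kept$id[match(levels(f), kept$seq)],
                        stringsAsFactors = FALSE)
  uniques <- uniques[order(-uniques$abundance, uniques$seq), , drop = FALSE]
  rownames(uniques) <- NULL
  list(uniques = uniques,
       rejects = data.frame(id = merged$id[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Chimera-flagging parameters
#' @param skew minimum parent/query abundance ratio.
#' @param min_diff minimum improvement (matching positions) of the best
#'   two-parent model over the best single parent.
#' @param min_identity minimum identity of the chimeric model to the query.
#' @return a `chimera_params` list.
#' @export
chimera_params <- function(skew = 2, min_diff = 3L, min_identity = 0.99) {
  list(skew = skew, min_diff = as.integer(min_diff),
       min_identity = min_identity)
}

#' Flag two-parent (bimera) chimeras among unique sequences
#'
#' For each unique sequence, candidate parents are same-length uniques with
#' abundance >= `skew` times the query's. Over ordered parent pairs and
#' crossover points, the best chimeric model's matches are compared with the
#' best single parent's; the query is flagged iff the improvement is at
#' least `min_diff` positions and the chimeric model's identity to the query
#' is at least `min_identity`.
#'
#' @param uniques data frame from [screen_dereplicate()].
#' @param params [chimera_params()].
#' @return `uniques` with added columns `chimera`, `parent_left`,
#'   `parent_right`.
#' @export
flag_chimeras <- function(uniques, params = chimera_params()) {
  n <- nrow(uniques)
  uniques$chimera <- FALSE
  uniques$parent_left <- NA_character_
  uniques$parent_right <- NA_character_
  if (n < 3L) return(uniques)
  len <- nchar(uniques$seq)
  for (i in seq_len(n)) {
    cand <- which(uniques$abundance >= params$skew * uniques$abundance[i] &
                    len == len[i])
    cand <- setdiff(cand, i)
    if (length(cand) < 2L) next
    L <- len[i]
    q <- strsplit(uniques$seq[i], "", fixed = TRUE)[[1]]
    P <- matrix(unlist(strsplit(uniques$seq[cand], "", fixed = TRUE),
                       use.names = FALSE), nrow = length(cand), byrow = TRUE)
    eq <- P == matrix(q, length(cand), L, byrow = TRUE)
    pref <- t(apply(eq, 1L, cumsum))           # matches in q[1..x]
    tot <- pref[, L]
    best_single <- max(tot)
    # crossover after position x: left parent covers 1..x, right x+1..L
    lmax <- apply(pref[, -L, drop = FALSE], 2L, max)
    larg <- apply(pref[, -L, drop = FALSE], 2L, which.max)
    sufM <- tot - pref[, -L, drop = FALSE]     # matches in q[x+1..L]
    rmax <- apply(sufM, 2L, max)
    rarg <- apply(sufM, 2L, which.max)
    chim <- lmax + rmax
    x <- which.max(chim)
    improvement <- chim[x] - best_single
    identity <- chim[x] / L
    if (larg[x] != rarg[x] && improvement >= params$min_diff &&
        identity >= params$min_identity) {
      uniques$chimera[i] <- TRUE
      uniques$parent_left[i] <- uniques$rep_id[cand[larg[x]]]
      uniques$parent_right[i] <- uniques$rep_id[cand[rarg[x]]]
    }
  }
  uniques
}

#' Species detection rule
#' @param min_reads minimum classified read count for detection.
#' @param min_fraction minimum fraction of kept reads for detection.
#' @return a `detection_rule` list.
#' @export
detection_rule <- function(min_reads = 10L, min_fraction = 0.001) {
  list(min_reads = as.integer(min_reads), min_fraction = min_fraction)
}

#' Profile a pooled sample from its unique sequences
#'
#' Classifies each non-chimeric unique with the Bayes model, aggregates
#' abundances per species (calls accepted at species rank), and applies the
#' detection rule: a species is detected iff its read count >= `min_reads`
#' and its proportion of kept reads >= `min_fraction`. Each off-target
#' model is applied the same way; uniques accepted at genus rank or deeper
#' against an off-target model are reported as off-target hits.
#'
#' @param uniques data frame from [flag_chimeras()] (chimeras are excluded)
#'   or [screen_dereplicate()].
#' @param model `bayes_model` for the target taxon.
#' @param params [classifier_params()].
#' @param detection [detection_rule()].
#' @param off_target_models named list of `bayes_model`s for non-target
#'   screens.
#' @return a `sample_profile` list: `table` (species, reads, proportion,
#'   detected), `unclassified_reads`, `total_reads`, `off_target` (data
#'   frame model, reads), `params`.
#' @export
profile_pool <- function(uniques, model, params = classifier_params(),
                         detection = detection_rule(),
                         off_target_models = list()) {
  if ("chimera" %in% names(uniques)) {
    uniques <- uniques[!uniques$chimera, , drop = FALSE]
  }
  total <- sum(uniques$abundance)
  calls <- classify_bayes_batch(model, uniques$seq, params)
  sp <- vapply(calls, function(cl) {
    conf <- cl$confidence[cl$rank == "species"]
    if (!is.na(conf) && conf >= params$confidence)
      cl$taxon[cl$rank == "species"] else NA_character_
  }, character(1))
  classified <- !is.na(sp)
  counts <- tapply(uniques$abundance[classified], sp[classified], sum)
  tab <- data.frame(species = names(counts),
                    reads = as.integer(counts),
                    proportion = as.numeric(counts) / total,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$detected <- tab$reads >= detection$min_reads &
    tab$proportion >= detection$min_fraction
  tab <- tab[order(-tab$reads, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  off <- lapply(names(off_target_models), function(nm) {
    oc <- classify_bayes_batch(off_target_models[[nm]], uniques$seq, params)
    hit <- vapply(oc, function(cl) {
      attr(cl, "accepted_rank") %in% c("species", "genus")
    }, logical(1))
    data.frame(model = nm, reads = sum(uniques$abundance[hit]),
               stringsAsFactors = FALSE)
  })
  structure(list(table = tab,
                 unclassified_reads = total - sum(tab$reads),
                 total_reads = total,
                 off_target = if (length(off)) do.call(rbind, off)
                              else data.frame(model = character(),
                                              reads = integer()),
                 params = list(classifier = params, detection = detection)),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile:", x$total_reads, "reads;",
      sum(x$table$detected), "species detected\n")
  print(x$table)
  invisible(x)
}

#' Run the full pooled-sample pipeline
#'
#' Strip tails/primers, merge, screen against the primer pair's expected
#' insert length, dereplicate, flag chimeras, classify and profile.
#'
#' @param pairs a `read_pairs` data frame.
#' @param pair primer pair.
#' @param model `bayes_model` trained on the trimmed reference library.
#' @param tails universal tails.
#' @param cparams [classifier_params()].
#' @param detection [detection_rule()].
#' @param l_expected expected insert length; default inferred from the
#'   model's training sequences (their modal length).
#' @param delta screening length slack.
#' @param off_target_models named list of off-target `bayes_model`s.
#' @return list with `profile` and all intermediate stage outputs
#'   (`stripped`, `merged`, `screened`, `uniques`) plus accounting.
#' @export
run_read_pipeline <- function(pairs, pair, model, tails = universal_tails(),
                              cparams = classifier_params(),
                              detection = detection_rule(),
                              l_expected = NULL, delta = 10L,
                              off_target_models = list()) {
  stripped <- strip_primers_tails(pairs, pair, tails)
  merged <- merge_pairs(stripped$pairs)
  if (is.null(l_expected)) {
    lens <- nchar(merged$merged$seq)
    l_expected <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  }
  screened <- screen_dereplicate(merged$merged,
                                 screen_params(l_expected, delta))
  uniques <- flag_chimeras(screened$uniques)
  profile <- profile_pool(uniques, model, cparams, detection,
                          off_target_models)
  list(profile = profile, stripped = stripped, merged = merged,
       screened = screened, uniques = uniques,
       accounting = list(
         input_pairs = nrow(pairs),
         stripped_kept = nrow(stripped$pairs),
         merged = nrow(merged$merged),
         merge_failures = nrow(merged$failures),
         screened_kept = sum(screened$uniques$abundance),
         screen_rejects = nrow(screened$rejects),
         chimeras = sum(uniques$chimera)))
}
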