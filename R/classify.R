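# Taxonomic assignment of mini-barcode sequences: a word-presence
# (k-mer) naive-Bayes classifier with bootstrap confidence, in the style of
# the RDP classifier, and a top-hit identity classifier.

.RANKS <- c("species", "genus", "family", "order")

#' Classifier parameters
#'
#' @param confidence confidence threshold c in \[0, 1\] for accepting a call
#'   at a rank.
#' @param bootstrap number of bootstrap trials B.
#' @param word_fraction fraction of the query's distinct words drawn (with
#'   replacement) per trial.
#' @param seed RNG seed making calls reproducible.
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(confidence = 0.8, bootstrap = 100L,
                              word_fraction = 1 / 8, seed = 1L) {
  stopifnot(confidence >= 0, confidence <= 1, bootstrap >= 1L,
            word_fraction > 0, word_fraction <= 1)
  list(confidence = confidence, bootstrap = as.integer(bootstrap),
       word_fraction = word_fraction, seed = as.integer(seed))
}

#' Train the naive-Bayes k-mer word model
#'
#' Words are the distinct overlapping k-mers of each training sequence
#' (presence, not frequency). With `m(w,S)` the number of species-S
#' sequences containing word w, `M(S)` the species' sequence count, `n(w)`
#' the word's document count and `N` the total sequence count, the model
#' stores the word prior `P(w) = (n(w)+0.5)/(N+1)` and conditional
#' `P(w|S) = (m(w,S)+P(w))/(M(S)+1)`.
#'
#' Training leaves are species; records lacking a species but carrying a
#' genus train a `"<genus> sp."` leaf so they still inform genus-level
#' calls. Sequences shorter than k are rejected and logged.
#'
#' @param lib a `ref_library` (trimmed to the amplicon region) or a
#'   [nuc_records()] data frame plus `taxonomy`.
#' @param k word size.
#' @param taxonomy taxonomy data frame when `lib` is a plain record set.
#' @return a `bayes_model` list.
#' @export
train_bayes <- function(lib, k = 8L, taxonomy = NULL) {
  records <- if (inherits(lib, "ref_library")) lib$records else lib
  if (inherits(lib, "ref_library")) taxonomy <- lib$taxonomy
  if (is.null(taxonomy)) stop("taxonomy required for training")
  i <- match(records$id, taxonomy$id)
  if (anyNA(i)) {
    stop("records without taxonomy: ",
         paste(utils::head(records$id[is.na(i)]), collapse = ", "))
  }
  leaf <- ifelse(is.na(taxonomy$species[i]),
                 paste(taxonomy$genus[i], "sp."), taxonomy$species[i])
  if (anyNA(taxonomy$genus[i])) {
    stop("training records must be identified at least to genus")
  }
  short <- nchar(records$seq) < k
  log <- data.frame(id = records$id[short],
                    action = rep("reject", sum(short)),
                    reason = rep("shorter_than_k", sum(short)),
                    stringsAsFactors = FALSE)
  records <- records[!short, , drop = FALSE]
  leaf <- leaf[!short]
  if (!nrow(records)) stop("no trainable sequences of length >= k")
  species <- sort(unique(leaf))
  words_per_seq <- lapply(records$seq, .kmers, k = k)
  vocab <- sort(unique(unlist(words_per_seq)))
  n_w <- integer(length(vocab))
  m <- matrix(0L, nrow = length(vocab), ncol = length(species),
              dimnames = list(NULL, species))
  si <- match(leaf, species)
  for (j in seq_along(words_per_seq)) {
    wi <- match(words_per_seq[[j]], vocab)
    n_w[wi] <- n_w[wi] + 1L
    m[wi, si[j]] <- m[wi, si[j]] + 1L
  }
  M <- as.integer(table(factor(leaf, levels = species)))
  N <- nrow(records)
  prior <- (n_w + 0.5) / (N + 1)
  # log P(w|S) for in-vocabulary words; out-of-vocabulary words contribute
  # log(0.5/(N+1)) - log(M(S)+1) per species.
  logL <- log(m + prior) - matrix(log(M + 1), nrow = length(vocab),
                                  ncol = length(species), byrow = TRUE)
  # species -> lineage rollup (first occurrence wins)
  lin <- taxonomy[!duplicated(ifelse(is.na(taxonomy$species),
                                     paste(taxonomy$genus, "sp."),
                                     taxonomy$species)), , drop = FALSE]
  key <- ifelse(is.na(lin$species), paste(lin$genus, "sp."), lin$species)
  li <- match(species, key)
  lineage <- data.frame(species = species,
                        genus = lin$genus[li], family = lin$family[li],
                        order = lin$order[li], stringsAsFactors = FALSE)
  structure(list(k = as.integer(k), vocab = vocab, m = m, M = M,
                 n_w = n_w, N = N, prior = prior, logL = logL,
                 species = species, lineage = lineage, log = log),
            class = "bayes_model")
}

#' @export
print.bayes_model <- function(x, ...) {
  cat("bayes_model: k =", x$k, "|", length(x$species), "species leaves |",
      x$N, "sequences |", length(x$vocab), "words\n")
  invisible(x)
}

# Per-query word log-likelihood matrix (rows = query words incl. unseen,
# cols = species), already including the -log(M+1) normalizer.
.query_word_matrix <- function(model, words) {
  wi <- match(words, model$vocab)
  Q <- matrix(log(0.5 / (model$N + 1)) - rep(log(model$M + 1),
                                             each = length(words)),
              nrow = length(words), ncol = length(model$species))
  seen <- !is.na(wi)
  if (any(seen)) Q[seen, ] <- model$logL[wi[seen], , drop = FALSE]
  Q
}

.rollup <- function(model, sp, rank) {
  if (rank == "species") return(sp)
  model$lineage[[rank]][match(sp, model$lineage$species)]
}

#' Classify a query with bootstrap confidence
#'
#' The candidate path is the maximum-likelihood species over all of the
#' query's distinct words (ties broken lexicographically). Each bootstrap
#' trial samples `ceiling(W * word_fraction)` of the W distinct words with
#' replacement and re-scores; a trial votes for its unique best species
#' (trials whose maximum is tied between species abstain). Confidence at a
#' rank is the fraction of trials whose winner maps to the candidate's
#' taxon at that rank, so confidence is non-decreasing from species to
#' order. The accepted rank is the deepest rank with confidence >= c.
#'
#' @param model a `bayes_model` from [train_bayes()].
#' @param query an IUPAC sequence string (length >= k).
#' @param params [classifier_params()].
#' @return a `bayes_call`: data frame (rank, taxon, confidence) with
#'   attributes `accepted_rank` and `accepted_taxon`.
#' @export
classify_bayes <- function(model, query, params = classifier_params()) {
  withr::with_seed(params$seed, classify_bayes_(model, query, params))
}

# Internal: no reseeding, used for batch classification under one stream.
classify_bayes_ <- function(model, query, params) {
  query <- .norm_seq(query)
  if (nchar(query) < model$k) stop("query shorter than word size k")
  words <- .kmers(query, model$k)
  W <- length(words)
  Q <- .query_word_matrix(model, words)
  full <- colSums(Q)
  best <- which(full == max(full))
  cand <- model$species[best[order(model$species[best])][1L]]
  msub <- as.integer(ceiling(W * params$word_fraction))
  B <- params$bootstrap
  idx <- matrix(sample.int(W, msub * B, replace = TRUE), nrow = msub)
  votes <- character(B)
  for (b in seq_len(B)) {
    sc <- colSums(Q[idx[, b], , drop = FALSE])
    mx <- which(sc == max(sc))
    votes[b] <- if (length(mx) == 1L) model$species[mx] else NA_character_
  }
  conf <- vapply(.RANKS, function(r) {
    tgt <- .rollup(model, cand, r)
    if (is.na(tgt)) return(NA_real_)
    mean(!is.na(votes) & .rollup(model, votes, r) == tgt, na.rm = FALSE)
  }, numeric(1))
  # enforce monotonicity across NA ranks (missing lineage levels)
  taxa <- vapply(.RANKS, function(r) .rollup(model, cand, r), character(1))
  call <- data.frame(rank = .RANKS, taxon = taxa, confidence = conf,
                     stringsAsFactors = FALSE, row.names = NULL)
  ok <- !is.na(call$confidence) & call$confidence >= params$confidence
  accepted <- if (any(ok)) call$rank[which(ok)[1L]] else "unclassified"
  attr(call, "accepted_rank") <- accepted
  attr(call, "accepted_taxon") <- if (accepted == "unclassified")
    NA_character_ else call$taxon[call$rank == accepted]
  class(call) <- c("bayes_call", "data.frame")
  call
}

#' Classify many queries under one seeded RNG stream
#'
#' @param model a `bayes_model`.
#' @param queries character vector of sequences.
#' @param params [classifier_params()]; `params$seed` seeds the single
#'   stream, so results are reproducible as a batch.
#' @return list of `bayes_call` objects.
#' @export
classify_bayes_batch <- function(model, queries, params = classifier_params()) {
  withr::with_seed(params$seed,
                   lapply(queries, classify_bayes_, model = model,
                          params = params))
}

#' Top-hit identity classification
#'
#' Computes identity (as in [seq_identity()]) between the query and every
#' reference; the tie set is all references within `tie_epsilon` of the best
#' identity, and the assignment is the deepest rank on which the tie set is
#' unanimous.
#'
#' @param lib a `ref_library` with taxonomy, or [nuc_records()] +
#'   `taxonomy`.
#' @param query sequence string.
#' @param tie_epsilon identity slack defining the tie set (default 0).
#' @param taxonomy taxonomy when `lib` is a plain record set.
#' @return a `tophit_result` list: `best_identity`, `ties` (data frame of
#'   tied references with lineages), `rank`, `taxon`.
#' @export
classify_tophit <- function(lib, query, tie_epsilon = 0, taxonomy = NULL) {
  records <- if (inherits(lib, "ref_library")) lib$records else lib
  if (inherits(lib, "ref_library")) taxonomy <- lib$taxonomy
  if (!nrow(records)) stop("empty reference library")
  query <- .norm_seq(query)
  idn <- vapply(records$seq, seq_identity, numeric(1), b = query,
                USE.NAMES = FALSE)
  best <- max(idn)
  tie <- which(idn >= best - tie_epsilon)
  i <- match(records$id[tie], taxonomy$id)
  ties <- data.frame(id = records$id[tie], identity = idn[tie],
                     order = taxonomy$order[i], family = taxonomy$family[i],
                     genus = taxonomy$genus[i], species = taxonomy$species[i],
                     stringsAsFactors = FALSE)
  rank <- NA_character_; taxon <- NA_character_
  for (r in .RANKS) {
    vals <- unique(ties[[r]])
    if (length(vals) == 1L && !anyNA(vals)) { rank <- r; taxon <- vals; break }
  }
  structure(list(best_identity = best, ties = ties, rank = rank,
                 taxon = taxon),
            class = "tophit_result")
}

#' Serialize / restore a Bayes model as JSON-lines
#'
#' Line 1 is a version/metadata header; subsequent lines carry one word
#' each with its document count and per-species presence counts.
#'
#' @param model a `bayes_model`.
#' @param path file path.
#' @return `path` invisibly (`write_`), or a `bayes_model` (`read_`).
#' @export
write_bayes_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    format = "batbarcode-bayes", version = 1L, k = model$k, N = model$N,
    M = model$M, species = model$species, lineage = model$lineage),
    auto_unbox = TRUE), con)
  for (i in seq_along(model$vocab)) {
    nz <- which(model$m[i, ] > 0L)
    writeLines(jsonlite::toJSON(list(w = model$vocab[i], n = model$n_w[i],
                                     s = nz, c = model$m[i, nz]),
                                auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' @rdname write_bayes_model
#' @export
read_bayes_model <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "batbarcode-bayes")) {
    stop("not a batbarcode Bayes model file: ", path)
  }
  vocab <- character(length(lines) - 1L)
  n_w <- integer(length(vocab))
  m <- matrix(0L, nrow = length(vocab), ncol = length(hdr$species),
              dimnames = list(NULL, hdr$species))
  for (i in seq_along(vocab)) {
    rec <- jsonlite::fromJSON(lines[i + 1L])
    vocab[i] <- rec$w; n_w[i] <- rec$n
    m[i, rec$s] <- as.integer(rec$c)
  }
  N <- hdr$N
  M <- as.integer(hdr$M)
  prior <- (n_w + 0.5) / (N + 1)
  logL <- log(m + prior) - matrix(log(M + 1), nrow = length(vocab),
                                  ncol = length(hdr$species), byrow = TRUE)
  structure(list(k = hdr$k, vocab = vocab, m = m, M = M, n_w = n_w, N = N,
                 prior = prior, logL = logL, species = hdr$species,
                 lineage = as.data.frame(hdr$lineage,
                                         stringsAsFactors = FALSE),
                 log = data.frame()),
            class = "bayes_model")
}
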