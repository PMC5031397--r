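# Evaluation framework: leave-out cross-validation with correct/false
# positive/false negative accounting, confidence-threshold sweeps, panel
# resolution scoring and mock-community detection metrics.

#' Leave-out evaluation design
#'
#' @param p held-out fraction per replicate (0 < p < 1).
#' @param replicates number of random subsamples R.
#' @param ranks ranks evaluated.
#' @param seed RNG seed for the subsampling.
#' @return an `eval_design` list.
#' @export
eval_design <- function(p = 0.05, replicates = 5L,
                        ranks = c("genus", "species"), seed = 1L) {
  stopifnot(p > 0, p < 1, replicates >= 1L,
            all(ranks %in% c("order", "family", "genus", "species")))
  list(p = p, replicates = as.integer(replicates), ranks = ranks,
       seed = as.integer(seed))
}

# Score held-out calls at one rank and threshold. truth may be NA (held-out
# record unidentified at that rank): such records can only be FP or FN.
.score_cells <- function(taxa, confs, truth, threshold) {
  classified <- !is.na(confs) & confs >= threshold
  correct <- classified & !is.na(truth) & !is.na(taxa) & taxa == truth
  fp <- classified & !correct
  fn <- !classified
  n <- length(taxa)
  c(correct = 100 * sum(correct) / n, false_positive = 100 * sum(fp) / n,
    false_negative = 100 * sum(fn) / n)
}

# Shared engine: per replicate, dereplicate at 100% identity, hold out
# ceil(p*n) uniformly at random, train on the rest, classify the held-out
# amplicon regions once, then threshold the stored confidences.
.leave_out_engine <- function(lib, design, cparams, thresholds, k = 8L) {
  records <- lib$records
  taxonomy <- lib$taxonomy
  derep <- greedy_cluster(records, cluster_params(1.0))
  records <- records[records$id %in% derep$centroids, , drop = FALSE]
  rows <- list()
  withr::with_seed(design$seed, {
    for (rep in seq_len(design$replicates)) {
      n <- nrow(records)
      hold <- sample.int(n, ceiling(design$p * n))
      train_rec <- records[-hold, , drop = FALSE]
      test_rec <- records[hold, , drop = FALSE]
      model <- train_bayes(ref_library(
        train_rec, taxonomy[taxonomy$id %in% train_rec$id, , drop = FALSE]),
        k = k)
      calls <- classify_bayes_batch(model, test_rec$seq, cparams)
      ti <- match(test_rec$id, taxonomy$id)
      for (rank in design$ranks) {
        taxa <- vapply(calls, function(cl) cl$taxon[cl$rank == rank],
                       character(1))
        confs <- vapply(calls, function(cl) cl$confidence[cl$rank == rank],
                        numeric(1))
        truth <- taxonomy[[rank]][ti]
        for (th in thresholds) {
          cell <- .score_cells(taxa, confs, truth, th)
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = rep, rank = rank, threshold = th,
            n = length(hold), correct = cell[["correct"]],
            false_positive = cell[["false_positive"]],
            false_negative = cell[["false_negative"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Leave-out cross-validation of the classifier
#'
#' Per replicate: dereplicate the library at 100% identity, hold out
#' `ceiling(p * n)` sequences uniformly at random (seeded), train on the
#' rest and classify the held-out sequences. At each rank a held-out
#' sequence is scored correct (classified at the rank to its true taxon),
#' false positive (classified at the rank to another taxon) or false
#' negative (not classified at the rank); the three percentages sum to 100.
#' Held-out species absent from training remain in the denominator.
#'
#' @param lib a `ref_library` trimmed to the amplicon region, with taxonomy.
#' @param design [eval_design()].
#' @param cparams [classifier_params()]; `cparams$confidence` is the single
#'   threshold evaluated.
#' @param k classifier word size.
#' @return an `eval_report` data frame (replicate, rank, threshold, n,
#'   correct, false_positive, false_negative; percentages).
#' @export
leave_out_eval <- function(lib, design = eval_design(),
                           cparams = classifier_params(), k = 8L) {
  .leave_out_engine(lib, design, cparams, cparams$confidence, k)
}

#' Confidence-threshold sweep of the leave-out evaluation
#'
#' Bootstrap confidences are computed once per held-out query and
#' re-thresholded, so rows differ only by the acceptance threshold.
#'
#' @param lib a `ref_library` trimmed to the amplicon region.
#' @param design [eval_design()].
#' @param thresholds thresholds in \[0, 1\] (default 0.5 to 1.0 step 0.05).
#' @param cparams [classifier_params()] (its `confidence` is ignored).
#' @param k classifier word size.
#' @return an `eval_report` data frame with one row per
#'   replicate x rank x threshold.
#' @export
threshold_sweep <- function(lib, design = eval_design(),
                            thresholds = seq(0.5, 1.0, by = 0.05),
                            cparams = classifier_params(), k = 8L) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  .leave_out_engine(lib, design, cparams, thresholds, k)
}

#' Panel resolution of a one-barcode-per-species panel
#'
#' Each species' barcode is compared leave-self-out against the rest of the
#' panel. A species is species-resolved iff no other species carries an
#' identical barcode (identity 1.0); otherwise it is congener-shared when
#' all identical-barcode species are of its genus, else cross-genus-shared.
#' The three categories partition the panel.
#'
#' @param panel a `ref_library` (one record per species) or [nuc_records()]
#'   + `taxonomy`.
#' @param taxonomy taxonomy when `panel` is a plain record set.
#' @param tie_epsilon identity slack treated as "shared" (default 0:
#'   exact barcode sharing).
#' @return a `resolution_report` list: `counts`, `percent`, `per_species`
#'   data frame (species, category, shared_with).
#' @export
panel_resolution <- function(panel, taxonomy = NULL, tie_epsilon = 0) {
  records <- if (inherits(panel, "ref_library")) panel$records else panel
  if (inherits(panel, "ref_library")) taxonomy <- panel$taxonomy
  ti <- match(records$id, taxonomy$id)
  species <- taxonomy$species[ti]
  genus <- taxonomy$genus[ti]
  if (anyNA(species)) stop("panel records must all be identified to species")
  if (anyDuplicated(species)) {
    stop("panel must contain one record per species; duplicated: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  n <- nrow(records)
  # fast path: equal-length panel -> one-hot identity matrix
  lens <- nchar(records$seq)
  if (length(unique(lens)) == 1L) {
    Lm <- .seq_mask_matrix(records$seq)
    X <- cbind(Lm == 1L, Lm == 2L, Lm == 4L, Lm == 8L) * 1
    idM <- tcrossprod(X) / lens[1]
  } else {
    idM <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        idM[i, j] <- idM[j, i] <- seq_identity(records$seq[i], records$seq[j])
      }
    }
  }
  diag(idM) <- 0
  category <- character(n)
  shared_with <- character(n)
  for (i in seq_len(n)) {
    sharers <- which(idM[i, ] >= 1 - tie_epsilon)
    if (!length(sharers)) {
      category[i] <- "species_resolved"
    } else if (all(genus[sharers] == genus[i])) {
      category[i] <- "congener_shared"
      shared_with[i] <- paste(species[sharers], collapse = ";")
    } else {
      category[i] <- "cross_genus_shared"
      shared_with[i] <- paste(species[sharers], collapse = ";")
    }
  }
  lv <- c("species_resolved", "congener_shared", "cross_genus_shared")
  counts <- table(factor(category, levels = lv))
  structure(list(counts = counts, percent = 100 * as.numeric(counts) / n,
                 per_species = data.frame(species = species,
                                          category = category,
                                          shared_with = shared_with,
                                          stringsAsFactors = FALSE)),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  lv <- names(x$counts)
  for (i in seq_along(lv)) {
    cat(sprintf("%-20s %5d (%.1f%%)\n", lv[i], x$counts[i], x$percent[i]))
  }
  invisible(x)
}

#' Detection sensitivity and specificity of a sample profile
#'
#' Sensitivity is the percentage of truly present species detected;
#' specificity is 100 when no detected species lies outside the truth set,
#' otherwise the percentage of detected species that are true.
#'
#' @param profile a `sample_profile` from [profile_pool()].
#' @param truth character vector of species truly present (non-empty).
#' @return list with `sensitivity` and `specificity` (percent), plus the
#'   detected species vector.
#' @export
detection_metrics <- function(profile, truth) {
  if (!length(truth)) stop("empty truth set")
  detected <- profile$table$species[profile$table$detected]
  sens <- 100 * sum(truth %in% detected) / length(truth)
  spec <- if (!length(detected)) 100
          else 100 * sum(detected %in% truth) / length(detected)
  list(sensitivity = sens, specificity = spec, detected = detected)
}

#' Write an evaluation report as TSV
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
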