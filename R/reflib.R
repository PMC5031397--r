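# Reference-library construction: curation filters, greedy identity
# clustering and primer-anchored trimming to the mini-barcode region.

#' Curation parameters
#'
#' @param min_len minimum sequence length (nt).
#' @param max_len optional maximum length (nt).
#' @param require_marker marker label records must carry (e.g. `"COI-5P"`),
#'   or `NULL` to skip the marker filter.
#' @param min_rank_depth `"genus"` or `"species"`: minimum lineage depth, or
#'   `NULL` to skip the taxonomy filter.
#' @param drop_ambiguous drop sequences containing non-ACGT characters.
#' @return a `curation_params` list.
#' @export
curation_params <- function(min_len = 500L, max_len = NULL,
                            require_marker = NULL, min_rank_depth = NULL,
                            drop_ambiguous = TRUE) {
  if (!is.null(max_len) && min_len > max_len) stop("min_len > max_len")
  if (!is.null(min_rank_depth)) {
    stopifnot(min_rank_depth %in% c("genus", "species"))
  }
  list(min_len = as.integer(min_len),
       max_len = if (is.null(max_len)) NULL else as.integer(max_len),
       require_marker = require_marker, min_rank_depth = min_rank_depth,
       drop_ambiguous = isTRUE(drop_ambiguous))
}

#' Shipped curation presets
#'
#' `"design"`: 500-700 nt with ambiguity drop (primer-design input pass);
#' `"reference"`: >= 500 nt, COI-5P marker, genus-or-deeper lineage
#' (classification-library pass).
#'
#' @param preset `"design"` or `"reference"`.
#' @return a [curation_params()] list.
#' @export
curation_preset <- function(preset = c("design", "reference")) {
  switch(match.arg(preset),
         design = curation_params(min_len = 500L, max_len = 700L,
                                  drop_ambiguous = TRUE),
         reference = curation_params(min_len = 500L, max_len = NULL,
                                     require_marker = "COI-5P",
                                     min_rank_depth = "genus",
                                     drop_ambiguous = TRUE))
}

#' Assemble a reference library object
#'
#' @param records [nuc_records()] data frame (may carry a `marker` column).
#' @param taxonomy taxonomy data frame (id + ranks), or `NULL`.
#' @param log provenance data frame (id, action, reason).
#' @return a `ref_library` list.
#' @export
ref_library <- function(records, taxonomy = NULL,
                        log = data.frame(id = character(),
                                         action = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE)) {
  if (anyDuplicated(records$id)) stop("duplicate record ids in library")
  structure(list(records = records, taxonomy = taxonomy, log = log),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat("ref_library:", nrow(x$records), "records;",
      if (is.null(x$taxonomy)) 0L else nrow(x$taxonomy), "lineages;",
      nrow(x$log), "provenance entries\n")
  invisible(x)
}

#' Curate records into a reference library
#'
#' Filters are applied per record in a fixed order -- marker, length,
#' ambiguity, taxonomy -- and the first failing filter is logged as the
#' rejection reason.
#'
#' @param records [nuc_records()] data frame, optionally with a `marker`
#'   column.
#' @param taxonomy taxonomy data frame (id + ranks), or `NULL`.
#' @param params [curation_params()].
#' @return a `ref_library` with kept records and a rejection log.
#' @export
curate <- function(records, taxonomy = NULL, params = curation_params()) {
  reason <- rep(NA_character_, nrow(records))
  if (!is.null(params$require_marker)) {
    marker <- if ("marker" %in% names(records)) records$marker
              else rep(NA_character_, nrow(records))
    bad <- is.na(marker) | marker != params$require_marker
    reason[is.na(reason) & bad] <- "marker"
  }
  len <- nchar(records$seq)
  bad <- len < params$min_len |
    (!is.null(params$max_len) & len > c(params$max_len, Inf)[1])
  reason[is.na(reason) & bad] <- "length"
  if (params$drop_ambiguous) {
    bad <- grepl("[^ACGT]", records$seq)
    reason[is.na(reason) & bad] <- "ambiguity"
  }
  if (!is.null(params$min_rank_depth)) {
    if (is.null(taxonomy)) stop("taxonomy required for min_rank_depth filter")
    i <- match(records$id, taxonomy$id)
    deep <- !is.na(i) & !is.na(taxonomy$genus[i])
    if (params$min_rank_depth == "species") {
      deep <- deep & !is.na(taxonomy$species[i])
    }
    reason[is.na(reason) & !deep] <- "taxonomy"
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rej <- records$id[!is.na(reason)]
  log <- data.frame(id = rej, action = "reject",
                    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  tax <- if (is.null(taxonomy)) NULL
         else taxonomy[taxonomy$id %in% kept$id, , drop = FALSE]
  ref_library(kept, tax, log)
}

#' Clustering parameters
#' @param identity_threshold pairwise identity threshold t in (0, 1].
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(identity_threshold = 0.99) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  list(identity_threshold = identity_threshold)
}

#' Pairwise sequence identity
#'
#' Matching columns over alignment columns of a global alignment. Equal
#' lengths align gaplessly (position-wise comparison); unequal lengths use a
#' Needleman-Wunsch global alignment with gap penalties high enough that
#' length-matched COI inputs stay gapless.
#'
#' @param a,b IUPAC sequence strings.
#' @return identity in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    return(mean(ca == cb))
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       gapOpening = 10, gapExtension = 4)
  as.numeric(Biostrings::pid(aln, type = "PID1")) / 100
}

#' Greedy centroid clustering at an identity threshold
#'
#' Records are visited in deterministic order (length descending, then id
#' ascending); each record joins the first existing centroid with identity
#' >= t, else founds a new centroid.
#'
#' @param records [nuc_records()] data frame.
#' @param params [cluster_params()].
#' @return list with `centroids` (record ids in creation order),
#'   `membership` (data frame id, centroid, identity) and `abundance`
#'   (named member counts per centroid).
#' @export
greedy_cluster <- function(records, params = cluster_params()) {
  ord <- order(-nchar(records$seq), records$id)
  recs <- records[ord, , drop = FALSE]
  t <- params$identity_threshold
  cent_id <- character(0)
  cent_seq <- character(0)
  member <- character(nrow(recs))
  ident <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    assigned <- FALSE
    for (j in seq_along(cent_id)) {
      idn <- seq_identity(recs$seq[i], cent_seq[j])
      if (idn >= t) {
        member[i] <- cent_id[j]; ident[i] <- idn; assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      cent_id <- c(cent_id, recs$id[i])
      cent_seq <- c(cent_seq, recs$seq[i])
      member[i] <- recs$id[i]; ident[i] <- 1
    }
  }
  list(centroids = cent_id,
       membership = data.frame(id = recs$id, centroid = member,
                               identity = ident, stringsAsFactors = FALSE),
       abundance = table(factor(member, levels = cent_id)))
}

#' Trim library records to the mini-barcode amplicon region
#'
#' Runs [insilico_pcr()] per record and replaces each sequence with its
#' product (`keep_primers = TRUE`) or insert (`FALSE`). Records the pair
#' does not amplify are excluded and logged.
#'
#' @param lib a `ref_library` or [nuc_records()] data frame.
#' @param pair primer pair (see [primer_pair()]).
#' @param params [scoring_params()].
#' @param keep_primers keep the primer footprints in the trimmed sequence?
#' @return a `ref_library` of trimmed records plus trim/exclusion log.
#' @export
trim_to_minibarcode <- function(lib, pair, params = scoring_params(),
                                keep_primers = FALSE) {
  records <- if (inherits(lib, "ref_library")) lib$records else lib
  taxonomy <- if (inherits(lib, "ref_library")) lib$taxonomy else NULL
  hits <- insilico_pcr(pair, records, params)
  i <- match(records$id, hits$ref_id)
  kept <- !is.na(i)
  trimmed <- records[kept, , drop = FALSE]
  trimmed$seq <- if (keep_primers) hits$product[i[kept]]
                 else hits$insert[i[kept]]
  trimmed$qual <- NA_character_
  miss <- attr(hits, "log")
  log <- rbind(
    data.frame(id = trimmed$id, action = "trim", reason = "amplified",
               stringsAsFactors = FALSE),
    if (!is.null(miss)) data.frame(id = miss$id, action = "exclude",
                                   reason = miss$reason,
                                   stringsAsFactors = FALSE))
  tax <- if (is.null(taxonomy)) NULL
         else taxonomy[taxonomy$id %in% trimmed$id, , drop = FALSE]
  ref_library(trimmed, tax, log)
}

#' Write a reference library to disk (FASTA + taxonomy TSV + provenance TSV)
#'
#' @param lib a `ref_library`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return named character vector of written paths, invisibly.
#' @export
write_ref_library <- function(lib, dir, stem = "library") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, paste0(stem, ".fasta")),
             taxonomy = file.path(dir, paste0(stem, ".taxonomy.tsv")),
             log = file.path(dir, paste0(stem, ".provenance.tsv")))
  write_fasta(lib$records, paths[["fasta"]])
  if (!is.null(lib$taxonomy)) write_taxonomy(lib$taxonomy, paths[["taxonomy"]])
  utils::write.table(lib$log, paths[["log"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
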