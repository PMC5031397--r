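# IUPAC nucleotide primitives, FASTA/FASTQ and taxonomy I/O, mitochondrial
# translation and pseudogene (NUMT) screening.

# Bit encoding of IUPAC base sets: A=1, C=2, G=4, T=8. A degenerate code's
# mask is the union of its member bases, so intersection tests are bitwAnd.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)
.IUPAC_POPCOUNT <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L,
                     1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)
# mask -> canonical IUPAC letter (index = mask value)
.MASK_LETTER <- c("A", "C", "M", "G", "R", "S", "V",
                  "T", "W", "Y", "H", "K", "D", "B", "N")

# Vertebrate mitochondrial code: TAA, TAG, AGA, AGG are stops.
.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

.norm_seq <- function(x) {
  x <- chartr("u", "t", x)
  x <- chartr("U", "T", toupper(x))
  x
}

.check_alphabet <- function(x, id = NULL) {
  chars <- unique(strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, names(.IUPAC_MASK))
  if (length(bad)) {
    stop("non-IUPAC symbol(s) ", paste(bad, collapse = ", "),
         if (!is.null(id)) paste0(" in record '", id, "'"), call. = FALSE)
  }
  invisible(TRUE)
}

# Integer mask vector for one sequence string.
.seq_mask <- function(x) {
  m <- .IUPAC_MASK[strsplit(x, "", fixed = TRUE)[[1]]]
  if (anyNA(m)) stop("non-IUPAC symbol in sequence", call. = FALSE)
  unname(m)
}

# Character-mask matrix for a vector of equal-length sequences (rows = seqs).
.seq_mask_matrix <- function(x) {
  n <- nchar(x[1L])
  if (any(nchar(x) != n)) stop("sequences must have equal length")
  m <- .IUPAC_MASK[unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)]
  if (anyNA(m)) stop("non-IUPAC symbol in sequence", call. = FALSE)
  matrix(m, nrow = length(x), ncol = n, byrow = TRUE)
}

#' Construct a set of nucleotide records
#'
#' The basic sequence container used throughout the package: a data frame
#' with columns `id`, `desc`, `seq` and (optionally) `qual`, a Phred+33
#' quality string of the same length as `seq`.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of IUPAC nucleotide sequences (U is
#'   normalized to T, case is normalized to upper).
#' @param desc free-text descriptions (default empty).
#' @param qual optional Phred+33 quality strings matching `seq` lengths.
#' @return a `nuc_records` data frame.
#' @export
nuc_records <- function(id, seq, desc = "", qual = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- .norm_seq(as.character(seq))
  for (i in seq_along(seq)) .check_alphabet(seq[i], id[i])
  qual <- as.character(qual)
  df <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                   seq = seq, qual = rep_len(qual, length(id)),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$qual) & nchar(df$qual) != nchar(df$seq)
  if (any(bad)) {
    stop("quality length differs from sequence length for: ",
         paste(df$id[bad], collapse = ", "))
  }
  class(df) <- c("nuc_records", "data.frame")
  df
}

#' Read a FASTA file
#'
#' Order-preserving; lowercase and U are normalized; duplicate ids are an
#' error. The part of the header before the first whitespace becomes `id`,
#' the remainder `desc`.
#'
#' @param path path to a FASTA file.
#' @return a [nuc_records()] data frame (possibly 0-row).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(nuc_records(character(), character()))
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- as.character(ss)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(id[empty], collapse = ", "),
         " in ", path)
  }
  nuc_records(id = id, seq = seqs, desc = desc)
}

#' Write records to a FASTA file
#'
#' @param records a [nuc_records()] data frame.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  hdr <- ifelse(nzchar(records$desc),
                paste(records$id, records$desc), records$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a FASTQ file.
#' @return a [nuc_records()] data frame with `qual` set.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(nuc_records(character(), character()))
  # Biostrings warns about dropping (empty) mcols when re-wrapping the
  # DNAStringSet it just parsed; nothing of ours is lost
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  nuc_records(id = id, seq = as.character(x), desc = desc,
              qual = as.character(Biostrings::quality(x)))
}

#' Write records to a FASTQ file (Phred+33)
#'
#' @param records a [nuc_records()] data frame; all `qual` must be set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (anyNA(records$qual)) stop("all records need quality strings for FASTQ")
  hdr <- ifelse(nzchar(records$desc),
                paste(records$id, records$desc), records$id)
  out <- character(4L * nrow(records))
  out[seq(1L, length(out), 4L)] <- paste0("@", hdr)
  out[seq(2L, length(out), 4L)] <- records$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- records$qual
  writeLines(out, path)
  invisible(path)
}

#' Convert a Phred+33 quality string to integer scores
#' @param qual a quality string.
#' @return integer vector of Phred scores.
#' @export
phred_ints <- function(qual) utf8ToInt(qual) - 33L

#' Convert integer Phred scores to a Phred+33 string
#' @param q integer vector of Phred scores (>= 0).
#' @return quality string.
#' @export
phred_chars <- function(q) intToUtf8(pmax(q, 0L) + 33L)

#' Do an observed base and an IUPAC code match?
#'
#' True iff the base sets intersect; `N` matches everything. Vectorized over
#' both arguments.
#'
#' @param observed_base,code single IUPAC letters.
#' @return logical.
#' @export
iupac_match <- function(observed_base, code) {
  a <- .IUPAC_MASK[toupper(observed_base)]
  b <- .IUPAC_MASK[toupper(code)]
  if (anyNA(a) || anyNA(b)) stop("non-IUPAC symbol")
  unname(bitwAnd(a, b) > 0L)
}

#' Reverse complement of IUPAC sequences
#'
#' Degenerate codes are complemented per the IUPAC table (R<->Y, K<->M,
#' B<->V, D<->H, W/S/N self-complementary). Vectorized.
#'
#' @param sequence character vector of IUPAC sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  sequence <- .norm_seq(sequence)
  for (s in sequence) .check_alphabet(s)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", sequence)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Per-position degeneracy product of an IUPAC sequence
#' @param sequence an IUPAC string.
#' @return numeric degeneracy (product of base-set sizes).
#' @export
degeneracy <- function(sequence) {
  prod(.IUPAC_POPCOUNT[.seq_mask(.norm_seq(sequence)) + 1L])
}

# Count codons whose every IUPAC resolution is a stop, for one frame.
.count_forced_stops <- function(mask, frame) {
  n <- length(mask)
  if (frame + 1L > n - 2L) return(0L)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  stops_mask <- lapply(.MITO_STOPS, .seq_mask)
  count <- 0L
  for (s in starts) {
    cod <- mask[s:(s + 2L)]
    # every resolution a stop  <=>  each base set is covered by the union of
    # stop codons compatible position-wise; check by enumerating resolutions
    bases <- lapply(cod, function(m) which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L))
    res <- expand.grid(bases, KEEP.OUT.ATTRS = FALSE)
    codons <- apply(res, 1L, function(r) paste(c("A", "C", "G", "T")[r],
                                               collapse = ""))
    if (all(codons %in% .MITO_STOPS)) count <- count + 1L
  }
  count
}

#' Screen a sequence for in-frame stop codons (NUMT / pseudogene check)
#'
#' Translates under the vertebrate mitochondrial code (stops TAA, TAG, AGA,
#' AGG). With `frame = "auto"` the frame (0, 1 or 2) minimizing the stop
#' count is chosen (smallest frame on ties). Degenerate codons count as stops
#' only when every IUPAC resolution is a stop.
#'
#' @param sequence an IUPAC nucleotide string, length >= 3.
#' @param frame `"auto"` or an integer 0, 1 or 2.
#' @return list with `status` ("pass"/"flagged"), `stop_count`,
#'   `chosen_frame`, and `per_frame` stop counts.
#' @export
pseudogene_screen <- function(sequence, frame = "auto") {
  sequence <- .norm_seq(sequence)
  if (nchar(sequence) < 3L) stop("sequence shorter than one codon")
  mask <- .seq_mask(sequence)
  frames <- 0:2
  per_frame <- vapply(frames, function(f) {
    if (nchar(sequence) - f < 3L) return(NA_integer_)
    .count_forced_stops(mask, f)
  }, integer(1))
  if (identical(frame, "auto")) {
    chosen <- frames[which.min(per_frame)]
  } else {
    chosen <- as.integer(frame)
    if (!chosen %in% frames) stop("frame must be 0, 1, 2 or 'auto'")
  }
  sc <- per_frame[chosen + 1L]
  list(status = if (isTRUE(sc > 0L)) "flagged" else "pass",
       stop_count = sc, chosen_frame = chosen, per_frame = per_frame)
}

#' Parse a BOLD-style lineage string
#'
#' Accepts `order;family;genus;species` (optionally with a subfamily between
#' family and genus, which is dropped). Missing ranks are left `NA`;
#' whitespace is trimmed. A species without a genus is an error.
#'
#' @param x a delimiter-separated lineage string.
#' @param sep field delimiter (default `";"`).
#' @return one-row data frame with columns order, family, genus, species and
#'   a logical `incomplete` flag.
#' @export
parse_bold_lineage <- function(x, sep = ";") {
  f <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  f[f == ""] <- NA_character_
  if (length(f) >= 5L) f <- f[c(1L, 2L, length(f) - 1L, length(f))]
  length(f) <- 4L
  names(f) <- c("order", "family", "genus", "species")
  if (!is.na(f[["species"]]) && is.na(f[["genus"]])) {
    stop("species set without genus in lineage: ", x)
  }
  data.frame(order = f[["order"]], family = f[["family"]],
             genus = f[["genus"]], species = f[["species"]],
             incomplete = anyNA(f), stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' Tab-separated `seq_id<TAB>order;family;genus;species` (QIIME-style).
#'
#' @param path path to taxonomy TSV.
#' @return data frame with columns id, order, family, genus, species.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(id = character(), order = character(),
                      family = character(), genus = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed taxonomy line ", bad[1], " in ", path)
  lin <- do.call(rbind, lapply(parts, function(p) parse_bold_lineage(p[2])))
  cbind(data.frame(id = vapply(parts, `[`, character(1), 1L),
                   stringsAsFactors = FALSE),
        lin[, c("order", "family", "genus", "species")])
}

#' Write a taxonomy table
#' @param taxonomy data frame with columns id, order, family, genus, species.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lin <- apply(taxonomy[, c("order", "family", "genus", "species")], 1L,
               function(r) paste(ifelse(is.na(r), "", r), collapse = ";"))
  writeLines(paste(taxonomy$id, lin, sep = "\t"), path)
  invisible(path)
}

# Distinct overlapping k-mers of a sequence.
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}
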