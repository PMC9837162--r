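#' Construct a PromoterCohort from sequences and metadata
#'
#' Low-level constructor; most users will call [readPromoterCohort()] or
#' [generateCohort()] instead. Sequences are uppercased and `U` is mapped to
#' `T` before validation, so RNA-style deposits are accepted; any character
#' outside the IUPAC DNA alphabet is a hard error.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of 90 bp
#'   promoter sequences.
#' @param info A data.frame or [S4Vectors::DataFrame] with columns
#'   `record_id`, `species`, `gene_family` (one of `albumin`, `beta_amylase`,
#'   `globulin`) and `group` (`food` or `non_food`), parallel to `sequences`.
#' @param provenance Free-text origin label.
#' @return A [PromoterCohort-class] object.
#' @examples
#' co <- PromoterCohort(
#'   sequences = paste0(strrep("ACGT", 22), "AT"),
#'   info = data.frame(record_id = "p1", species = "Zea mays",
#'                     gene_family = "globulin", group = "food")
#' )
#' co
#' @export
PromoterCohort <- function(sequences, info, provenance = "unspecified") {
  if (is.character(sequences)) {
    sequences <- .asDNAStringSet(sequences)
  }
  info <- S4Vectors::DataFrame(lapply(as.data.frame(info), as.character))
  names(sequences) <- info$record_id
  new("PromoterCohort", sequences = sequences, info = info,
      provenance = as.character(provenance))
}

## Normalize raw character sequences: uppercase, U -> T, then let
## DNAStringSet enforce the IUPAC alphabet.
.asDNAStringSet <- function(x) {
  x <- chartr("U", "T", toupper(x))
  tryCatch(
    Biostrings::DNAStringSet(x),
    error = function(e) {
      stop("sequence contains characters outside the IUPAC DNA alphabet: ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' @rdname PromoterCohort-class
#' @export
setMethod("recordIds", "PromoterCohort", function(x) as.character(x@info$record_id))

#' @rdname PromoterCohort-class
#' @export
setMethod("promoterSequences", "PromoterCohort", function(x) x@sequences)

#' @rdname PromoterCohort-class
#' @export
setMethod("cohortInfo", "PromoterCohort", function(x) x@info)

#' @rdname PromoterCohort-class
#' @export
setMethod("provenance", "PromoterCohort", function(x) x@provenance)

#' @rdname PromoterCohort-class
#' @export
setMethod("length", "PromoterCohort", function(x) length(x@sequences))

#' @rdname PromoterCohort-class
#' @param i Index (numeric, logical or record-id character) to subset by.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PromoterCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, recordIds(x))
  initialize(x, sequences = x@sequences[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "PromoterCohort", function(object) {
  info <- object@info
  cat(sprintf("PromoterCohort with %d record(s) of %d bp\n",
              length(object), PROMOTER_WIDTH))
  if (length(object)) {
    fam <- table(factor(info$gene_family, levels = GENE_FAMILIES))
    grp <- table(factor(info$group, levels = PLANT_GROUPS))
    cat("  gene_family:",
        paste(sprintf("%s=%d", names(fam), fam), collapse = " "), "\n")
    cat("  group:      ",
        paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
    cat("  species:    ", length(unique(info$species)), "unique\n")
  }
  cat("  provenance: ", object@provenance, "\n")
})

#' Read a promoter cohort from FASTA plus a metadata table
#'
#' Reads a multi-record FASTA of 90 bp proximal promoter sequences (wrapped
#' or unwrapped lines) and a tab-separated metadata table with a header line
#' `record_id  species  gene_family  group` (UTF-8, `#`-prefixed comment
#' lines ignored). FASTA ids and metadata `record_id`s must match one-to-one;
#' a record present in only one of the two sources is an error. Sequences are
#' uppercased and `U` is mapped to `T`; every sequence must be exactly 90 bp
#' and every metadata token must come from its closed vocabulary.
#'
#' Record order follows the FASTA file.
#'
#' @param fasta_path Path to the promoter FASTA file.
#' @param metadata_path Path to the tab-separated metadata file.
#' @param provenance Origin label stored in the cohort (defaults to the
#'   FASTA path).
#' @return A [PromoterCohort-class].
#' @seealso [writePromoterCohort()] for the inverse operation;
#'   [filterAmbiguous()] to drop records with IUPAC ambiguity codes.
#' @export
readPromoterCohort <- function(fasta_path, metadata_path,
                               provenance = fasta_path) {
  raw <- Biostrings::readBStringSet(fasta_path)
  ids <- names(raw)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every FASTA record must have a non-empty id", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", ids)  # id = first token of the header
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- .asDNAStringSet(as.character(raw))

  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            comment.char = "#", colClasses = "character",
                            quote = "", fileEncoding = "UTF-8")
  needed <- c("record_id", "species", "gene_family", "group")
  if (!all(needed %in% colnames(meta))) {
    stop("metadata must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$record_id)) {
    stop("duplicated record_id in metadata: ",
         paste(unique(meta$record_id[duplicated(meta$record_id)]),
               collapse = ", "), call. = FALSE)
  }
  only_fasta <- setdiff(ids, meta$record_id)
  only_meta <- setdiff(meta$record_id, ids)
  if (length(only_fasta) || length(only_meta)) {
    stop("FASTA and metadata ids do not match one-to-one",
         if (length(only_fasta)) paste0("; FASTA only: ",
                                        paste(only_fasta, collapse = ", ")),
         if (length(only_meta)) paste0("; metadata only: ",
                                       paste(only_meta, collapse = ", ")),
         call. = FALSE)
  }
  bad_len <- which(Biostrings::width(seqs) != PROMOTER_WIDTH)
  if (length(bad_len)) {
    stop(sprintf("sequence length must be %d bp; offending record(s): %s",
                 PROMOTER_WIDTH, paste(ids[bad_len], collapse = ", ")),
         call. = FALSE)
  }
  meta <- meta[match(ids, meta$record_id), needed, drop = FALSE]
  PromoterCohort(sequences = as.character(seqs), info = meta,
                 provenance = provenance)
}

#' Write a promoter cohort to FASTA plus a metadata table
#'
#' Writes the cohort's sequences as unwrapped FASTA (one sequence line per
#' record) and its metadata as tab-separated text with a header. Reading the
#' pair back with [readPromoterCohort()] reproduces the cohort exactly, and
#' writing the same cohort twice produces byte-identical files.
#'
#' @param cohort A [PromoterCohort-class].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `c(fasta_path, metadata_path)`.
#' @export
writePromoterCohort <- function(cohort, fasta_path, metadata_path) {
  stopifnot(is(cohort, "PromoterCohort"))
  Biostrings::writeXStringSet(promoterSequences(cohort), fasta_path,
                              width = 20000L)
  utils::write.table(as.data.frame(cohortInfo(cohort)), metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(fasta_path, metadata_path))
}

#' Remove promoters containing IUPAC ambiguity codes
#'
#' Partitions a cohort into records whose sequences consist solely of
#' A, C, G and T, and records containing any ambiguity code (R, Y, W, S, K,
#' M, B, D, H, V or N). Input order is preserved on both sides and the two
#' parts together are exactly the input, so the operation is idempotent.
#' Affinity estimation requires the kept part.
#'
#' @param cohort A [PromoterCohort-class].
#' @return A list with elements `kept` (a `PromoterCohort`) and `removed`
#'   (character vector of excluded record ids, possibly empty).
#' @export
filterAmbiguous <- function(cohort) {
  stopifnot(is(cohort, "PromoterCohort"))
  seqs <- promoterSequences(cohort)
  if (!length(seqs)) {
    return(list(kept = cohort, removed = character(0)))
  }
  acgt <- Biostrings::letterFrequency(seqs, letters = DNA_BASES)
  pure <- rowSums(acgt) == Biostrings::width(seqs)
  list(
    kept = cohort[which(pure)],
    removed = recordIds(cohort)[!pure]
  )
}

#' Split a cohort by gene family, group or species
#'
#' Returns one sub-cohort per observed label, keyed and ordered by sorted
#' label; within each sub-cohort the input record order is preserved. The
#' sub-cohorts are disjoint and together contain every input record.
#'
#' @param cohort A [PromoterCohort-class].
#' @param by One of `"gene_family"`, `"group"`, `"species"`.
#' @return Named list of `PromoterCohort` objects (empty list for an empty
#'   cohort).
#' @export
partitionCohort <- function(cohort,
                            by = c("gene_family", "group", "species")) {
  stopifnot(is(cohort, "PromoterCohort"))
  by <- match.arg(by)
  if (!length(cohort)) return(setNames(list(), character(0)))
  labels <- as.character(cohortInfo(cohort)[[by]])
  out <- lapply(sort(unique(labels)), function(lab) cohort[which(labels == lab)])
  names(out) <- sort(unique(labels))
  out
}
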