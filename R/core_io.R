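# Domain containers and flat-file readers/writers.
#
# The spot table dialect mirrors common PDQuest exports: tab-separated,
# UTF-8, "." decimal separator, first column the spot id, remaining
# columns named by sample id, missing intensities encoded as empty cells.

#' Construct and validate a sample sheet
#'
#' The sample sheet describes the gel design: which organ, which oxygen
#' condition and which biological replicate each quantified sample (gel
#' channel) belongs to.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param organ `"shoot"` or `"root"` per sample.
#' @param condition `"control"`, `"anoxia"` or `"reaeration"` per sample.
#' @param replicate Positive integer replicate index per sample.
#' @param gel_id Physical gel identifier; defaults to `sample_id`.
#' @return A `data.frame` with class `"sample_sheet"`.
#' @examples
#' sample_sheet(paste0("s", 1:6), "shoot",
#'              rep(c("control", "anoxia", "reaeration"), each = 2), rep(1:2, 3))
#' @export
sample_sheet <- function(sample_id, organ, condition, replicate,
                         gel_id = sample_id) {
  sheet <- data.frame(
    sample_id = as.character(sample_id),
    organ = as.character(organ),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    gel_id = as.character(gel_id),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

#' @rdname sample_sheet
#' @param sheet A data frame with the sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "organ", "condition", "replicate", "gel_id")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols))
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  bad_cond <- setdiff(unique(sheet$condition), CONDITIONS)
  if (length(bad_cond))
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         "; allowed: ", paste(CONDITIONS, collapse = ", "))
  bad_organ <- setdiff(unique(sheet$organ), ORGANS)
  if (length(bad_organ))
    stop("unknown organ(s): ", paste(bad_organ, collapse = ", "))
  if (any(sheet$replicate < 1L))
    stop("replicate indices must be positive")
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read or write a sample sheet TSV
#'
#' @param path File path of a tab-delimited sample sheet with columns
#'   `sample_id`, `organ`, `condition`, `replicate`, `gel_id`.
#' @return `read_sample_sheet` returns a validated sample sheet;
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  sheet$replicate <- as.integer(sheet$replicate)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a spot-intensity table
#'
#' The central container of the pipeline: a spots x samples matrix of
#' fluorescence intensities (arbitrary units) together with its sample
#' sheet and two state flags recording whether the values have been
#' log2-transformed and quantile-normalized. Missing intensities are
#' carried as `NA`, never as silent zeros.
#'
#' @param matrix Numeric matrix, rows spots, columns samples; rownames
#'   are spot ids and colnames sample ids matching `sheet$sample_id`.
#' @param sheet A [sample_sheet()].
#' @param log_transformed,normalized State flags.
#' @return An object of class `"spot_table"` with elements `spot_ids`,
#'   `matrix`, `sheet`, `log_transformed`, `normalized`.
#' @export
spot_table <- function(matrix, sheet, log_transformed = FALSE,
                       normalized = FALSE) {
  sheet <- validate_sample_sheet(sheet)
  if (is.null(rownames(matrix)))
    stop("spot matrix must carry spot ids as rownames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated spot id(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  miss <- setdiff(sheet$sample_id, colnames(matrix))
  if (length(miss))
    stop("sample(s) in sheet missing from matrix: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(matrix), sheet$sample_id)
  if (length(extra))
    message("ignoring unmatched matrix column(s): ",
            paste(extra, collapse = ", "))
  matrix <- matrix[, sheet$sample_id, drop = FALSE]
  if (!log_transformed && any(matrix < 0, na.rm = TRUE))
    stop("negative intensities are not allowed before log transformation")
  structure(
    list(spot_ids = rownames(matrix), matrix = matrix, sheet = sheet,
         log_transformed = log_transformed, normalized = normalized),
    class = "spot_table"
  )
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots x %d samples (%s%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$log_transformed) "log2" else "raw",
              if (x$normalized) ", quantile-normalized" else ""))
  cat("organs: ", paste(unique(x$sheet$organ), collapse = ", "),
      "; conditions: ", paste(unique(x$sheet$condition), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.spot_table <- function(x) dim(x$matrix)

#' Read a tab-delimited spot-intensity table
#'
#' @param path Tab-delimited file; first column the spot id, remaining
#'   columns named by sample id. Empty cells are read as missing.
#' @param sheet_path Path to the matching sample sheet TSV, or a sample
#'   sheet object given directly via `sheet`.
#' @param sheet Optional sample sheet object (overrides `sheet_path`).
#' @return A [spot_table()] with columns ordered as in the sheet.
#' @export
read_spot_table <- function(path, sheet_path = NULL, sheet = NULL) {
  if (is.null(sheet)) {
    if (is.null(sheet_path)) stop("either sheet_path or sheet is required")
    sheet <- read_sample_sheet(sheet_path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                           check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated spot id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  spot_table(m, sheet)
}

#' Write a spot table in the tab-delimited dialect
#'
#' Missing values are written as empty cells so that
#' [read_spot_table()] round-trips the matrix exactly.
#'
#' @param x A [spot_table()].
#' @param path Output path.
#' @export
write_spot_table <- function(x, path) {
  stopifnot(inherits(x, "spot_table"))
  # %.17g guarantees the decimal text reads back to the identical double
  chr <- matrix(ifelse(is.na(x$matrix), NA_character_,
                       sprintf("%.17g", x$matrix)),
                nrow = nrow(x$matrix), dimnames = dimnames(x$matrix))
  out <- data.frame(spot_id = x$spot_ids, chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Protein records
#'
#' A light tabular representation of identified proteins: accession,
#' amino-acid sequence (20-letter alphabet, uppercase), source organ and
#' the gel spots the protein was observed in (list column).
#'
#' @param accession Character vector.
#' @param sequence Uppercase amino-acid sequences.
#' @param organ Organ per record (`NA` allowed).
#' @param spot_ids List of character vectors (one per record) or `NULL`.
#' @return A `data.frame` with class `"protein_records"`.
#' @export
protein_records <- function(accession, sequence, organ = NA_character_,
                            spot_ids = NULL) {
  sequence <- toupper(as.character(sequence))
  bad <- grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), sequence)
  if (any(bad))
    stop("non-standard residue in sequence(s): ",
         paste(accession[bad], collapse = ", "))
  if (any(!nzchar(sequence))) stop("empty protein sequence")
  if (is.null(spot_ids)) spot_ids <- rep(list(character()), length(accession))
  rec <- data.frame(accession = as.character(accession),
                    sequence = sequence,
                    organ = rep_len(as.character(organ), length(accession)),
                    stringsAsFactors = FALSE)
  rec$spot_ids <- spot_ids
  class(rec) <- c("protein_records", "data.frame")
  rec
}

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of each header;
#' an optional `organ=` token in the header is honoured.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param organ Organ to assign when the headers carry none.
#' @return A [protein_records()] table.
#' @export
read_proteins <- function(path, organ = NA_character_) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  org <- rep(organ, length(aa))
  has_org <- regmatches(headers, regexpr("organ=[A-Za-z]+", headers))
  idx <- grepl("organ=[A-Za-z]+", headers)
  org[idx] <- sub("organ=", "", has_org)
  protein_records(acc, as.character(aa), org)
}

#' Write protein records to FASTA
#'
#' @param records A [protein_records()] table.
#' @param path Output FASTA path.
#' @export
write_proteins <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(is.na(records$organ), records$accession,
                      paste0(records$accession, " organ=", records$organ))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Merge exact-duplicate protein sequences
#'
#' Records with byte-identical sequences (a 100% identity threshold) are
#' merged; the retained record keeps the first accession and the union
#' of spot ids. By default duplicates are resolved within each organ
#' because organs are analyzed separately throughout the pipeline.
#'
#' @param records A [protein_records()] table.
#' @param by_organ Merge within organ (`TRUE`, default) or globally.
#' @return A deduplicated [protein_records()] table.
#' @export
dedup_sequences <- function(records, by_organ = TRUE) {
  key <- if (by_organ) paste(records$organ, records$sequence, sep = "\r")
         else records$sequence
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  keep <- vapply(groups, `[`, integer(1), 1L)
  out <- records[keep, , drop = FALSE]
  out$spot_ids <- lapply(groups, function(i)
    sort(unique(unlist(records$spot_ids[i]))))
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Summarize category assignments
#'
#' Counts and fractions of functional category labels (e.g. COG
#' letters), one row per category, fractions normalized over non-missing
#' labels. Categories present in `universe` but unobserved are reported
#' with zero counts.
#'
#' @param labels Character vector of category assignments (`NA` =
#'   unannotated, dropped from the denominator).
#' @param universe Optional character vector of all reportable
#'   categories.
#' @return A `data.frame` with columns `category`, `count`, `fraction`.
#' @export
summarize_categories <- function(labels, universe = NULL) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) {
    warning("no non-missing category labels; empty summary")
    return(data.frame(category = character(), count = integer(),
                      fraction = numeric()))
  }
  lev <- sort(unique(c(labels, universe)))
  counts <- table(factor(labels, levels = lev))
  data.frame(category = lev,
             count = as.integer(counts),
             fraction = as.numeric(counts) / length(labels),
             row.names = NULL)
}
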