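#' Read a gene-by-sample raw count matrix
#'
#' Expects the first column to hold gene identifiers and the header row to
#' hold sample identifiers.  The body must be non-negative integers; any
#' violation is reported with the offending gene/sample so malformed exports
#' fail loudly rather than silently.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Integer matrix, genes as rows, samples as columns, with unique
#'   dimnames.
#' @export
read_counts <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("count file needs a gene id column plus >=1 sample")
  gene_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(body)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric values in sample '", sample_ids[bad], "'")
  }
  bad <- which(body < 0 | body != round(body) | !is.finite(body),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count (negative, fractional or missing) at gene '",
         gene_ids[bad[1, 1]], "', sample '", sample_ids[bad[1, 2]], "'")
  storage.mode(body) <- "integer"
  dimnames(body) <- list(gene_ids, sample_ids)
  validate_counts(body)
}

#' Validate a count matrix
#'
#' @param counts Matrix of counts with gene rownames and sample colnames.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  counts
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: first column `gene_id`, one column per sample.
#'
#' @param counts Count matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' Requires columns `sample_id`, `patient_id` and `sample_type`; an optional
#' `region` column is carried through.  `sample_type` is normalized
#' case-insensitively, accepting both "tumor" and "tumour" spellings.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns sample_id, patient_id, sample_type
#'   (factor levels `normal`, `tumour`) and region.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_table(df)
}

#' Validate a sample table
#' @param df Data frame with sample_id, patient_id, sample_type columns.
#' @return Normalized data frame.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "patient_id", "sample_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  st <- tolower(as.character(df$sample_type))
  st[st == "tumor"] <- "tumour"
  bad <- setdiff(unique(st), c("tumour", "normal"))
  if (length(bad) > 0)
    stop("unknown sample_type token(s): ", paste(bad, collapse = ", "))
  df$sample_type <- st
  if (is.null(df$region)) df$region <- NA_character_
  df[, c("sample_id", "patient_id", "sample_type", "region")]
}

#' Read a clinical table
#'
#' Requires `patient_id`, `rfs_days` and `recurrence_event`; any further
#' columns are carried through as covariates.  Empty strings and "NA" are
#' both read as missing.
#'
#' @param path Path to a TSV file.
#' @return `data.frame`, one row per patient.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  need <- c("patient_id", "rfs_days", "recurrence_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  if (any(df$rfs_days < 0, na.rm = TRUE)) stop("rfs_days must be >= 0")
  if (!all(df$recurrence_event %in% c(0L, 1L)))
    stop("recurrence_event must be 0/1")
  df
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB-style GMT: one set per line, fields
#' `name<TAB>description<TAB>member...`.  Trailing empty fields are dropped
#' and duplicate members within a set are de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member genes; set descriptions
#'   in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    stop("duplicate gene-set name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("gene set with no members")
    members
  })
  names(sets) <- names_
  attr(sets, "description") <- stats::setNames(desc, names_)
  sets
}

#' Write a data frame as TSV with a header row
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
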