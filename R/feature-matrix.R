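# The samples-by-features container every preprocessing step transforms.

.stages <- c("raw", "filtered", "imputed", "standardized", "corrected")

#' Construct a feature matrix
#'
#' A light container for untargeted metabolomics intensities: a numeric
#' samples-by-features matrix (strictly positive where observed, `NA` for
#' missing), a per-sample analytical batch label, and a pipeline stage
#' marker. The stage marker enforces the fixed preprocessing order
#' `raw -> filtered -> imputed -> standardized -> corrected`; calling a step
#' out of order raises an error.
#'
#' @param values numeric matrix with sample row names and feature column
#'   names; `NA` marks missing cells.
#' @param batch factor (or vector) of batch labels, one per sample.
#' @param stage pipeline stage of `values`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, batch, stage = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  stage <- match.arg(stage, .stages)
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  batch <- as.factor(batch)
  if (length(batch) != nrow(values)) stop("one batch label per sample is required")
  if (stage %in% c("raw", "filtered", "imputed") &&
      any(values[!is.na(values)] <= 0)) {
    stop("observed intensities must be strictly positive before the log transform")
  }
  structure(list(values = values, batch = batch, stage = stage),
            class = "feature_matrix")
}

require_stage <- function(fm, allowed, op) {
  if (!fm$stage %in% allowed) {
    stop(sprintf("`%s` expects a matrix at stage %s, got \"%s\" (pipeline order is %s)",
                 op, paste(dQuote(allowed, FALSE), collapse = "/"), fm$stage,
                 paste(.stages, collapse = " -> ")), call. = FALSE)
  }
  invisible(fm)
}

#' @method print feature_matrix
#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, stage \"%s\"\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  batches: %s\n",
              paste(sprintf("%s (%d)", levels(x$batch), table(x$batch)), collapse = ", ")))
  nm <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm, 100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read feature-matrix artifacts
#'
#' The on-disk dialect is plain text: a TSV of intensities (rows = samples,
#' first column `sample_id`, one column per feature, empty cell = missing)
#' and a two-column batch map TSV (`sample_id`, `batch`).
#'
#' @param fm a [feature_matrix()].
#' @param values_path,batch_path file paths for the intensity TSV and batch
#'   map TSV.
#' @return `write_feature_matrix` returns the paths invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @param stage stage label to stamp on the matrix read back.
#' @export
write_feature_matrix <- function(fm, values_path, batch_path) {
  df <- data.frame(sample_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(data.frame(sample_id = rownames(fm$values), batch = as.character(fm$batch)),
              batch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(values_path, batch_path))
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(values_path, batch_path, stage = "raw") {
  df <- read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  bm <- read.delim(batch_path, stringsAsFactors = FALSE)
  feature_matrix(values, batch = bm$batch[match(df$sample_id, bm$sample_id)],
                 stage = stage)
}

#' Write / read cohort phenotype tables
#'
#' @param cohort a `cohort_table`.
#' @param path CSV file path.
#' @return the path invisibly, or the cohort read back.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$design <- attr(cohort, "design")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  design <- df$design[1]
  df$design <- NULL
  for (v in c("sex", "smoking", "alcohol")) {
    if (v %in% names(df)) {
      lev <- if (v == "sex") c("female", "male") else c("current", "former", "never")
      df[[v]] <- factor(df[[v]], levels = lev)
    }
  }
  rownames(df) <- df$sample_id
  structure(df, design = design, class = c("cohort_table", "data.frame"))
}

#' Write / read ground-truth tables
#'
#' @param truth a `truth_table` from [generate_metabolome()].
#' @param path JSON file path.
#' @return the path invisibly, or the truth table read back.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$foods <- lapply(x$foods, as.data.frame)
  x$outcomes <- lapply(x$outcomes, as.data.frame)
  structure(x, class = "truth_table")
}
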