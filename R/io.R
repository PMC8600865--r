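# Tabular input/output: expression matrices, clinical tables, RS-call tables.

# markers treated as missing in clinical exports (TCGA uses bracketed ones)
MISSING_MARKERS <- c("", "NA", "NaN", "[Not Available]", "[Discrepancy]")

#' Declare a continuous clinical covariate
#' @param name Column name in the clinical file.
#' @return A covariate declaration used by [read_clinical()].
#' @export
cov_continuous <- function(name) {
  structure(list(name = name, kind = "continuous"), class = "cov_spec")
}

#' Declare a categorical clinical covariate
#' @param name Column name in the clinical file.
#' @param levels Allowed levels, reference first unless `ref` is given.
#' @param ref Reference level (defaults to `levels[1]`).
#' @return A covariate declaration used by [read_clinical()].
#' @export
cov_categorical <- function(name, levels, ref = levels[1]) {
  stopifnot(ref %in% levels)
  structure(list(name = name, kind = "categorical",
                 levels = c(ref, setdiff(levels, ref)), ref = ref),
            class = "cov_spec")
}

#' Read a gene expression matrix
#'
#' Expects tab-separated text with gene ids in the first column and one
#' column per sample. Values are assumed to already be on a
#' log2(count + 1)-style normalized scale; no transformation is applied.
#' Duplicated gene rows are collapsed to the first occurrence with a warning.
#' Missing or non-numeric cells are an error: expression input must be
#' complete.
#'
#' @param path Path to the tab-separated file.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @export
read_expression <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("malformed expression header: need gene id column plus >= 1 sample")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in expression header")
  gene_ids <- raw[[1]]
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    warning(sprintf("%d duplicated gene id(s) collapsed to first occurrence: %s",
                    sum(dup), paste(unique(gene_ids[dup]), collapse = ", ")))
    raw <- raw[!dup, , drop = FALSE]
    gene_ids <- gene_ids[!dup]
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  vals
}

#' Read a clinical table against a covariate schema
#'
#' Tab-separated text, one row per sample. Required columns: `sample_id`,
#' `os_time`, `os_event`, `radiotherapy`. The empty string, `NA`, `NaN`,
#' `[Not Available]` and `[Discrepancy]` are all mapped to missing.
#' Categorical covariates are validated against their declared levels and
#' returned as factors with the declared reference level first.
#'
#' @param path Path to the tab-separated file.
#' @param schema List of covariate declarations from [cov_continuous()] /
#'   [cov_categorical()].
#' @return A `data.frame` with columns `sample_id` (character), `os_time`
#'   (numeric), `os_event` (0/1), `radiotherapy` (0/1) and one column per
#'   declared covariate; the schema is attached as attribute `"schema"`.
#' @export
read_clinical <- function(path, schema = list()) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  required <- c("sample_id", "os_time", "os_event", "radiotherapy")
  missing_cols <- setdiff(required, colnames(raw))
  if (length(missing_cols))
    stop("clinical table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  blank <- function(x) {
    x[x %in% MISSING_MARKERS] <- NA_character_
    x
  }
  marker_used <- vapply(raw, function(x) any(x %in% setdiff(MISSING_MARKERS, c("", "NA"))), logical(1))
  if (any(marker_used))
    message("bracketed missing markers mapped to NA in: ",
            paste(names(marker_used)[marker_used], collapse = ", "))
  out <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in clinical table")
  num_col <- function(col) {
    x <- blank(raw[[col]])
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' (sample %s)",
                   x[bad][1], col, out$sample_id[bad][1]))
    v
  }
  out$os_time <- num_col("os_time")
  out$os_event <- num_col("os_event")
  out$radiotherapy <- num_col("radiotherapy")
  if (any(!is.na(out$os_time) & out$os_time <= 0))
    stop("os_time must be positive where present")
  bad_event <- !is.na(out$os_event) & !(out$os_event %in% c(0, 1))
  if (any(bad_event))
    stop(sprintf("os_event outside {0,1}: value %s (sample %s)",
                 out$os_event[bad_event][1], out$sample_id[bad_event][1]))
  bad_rt <- !is.na(out$radiotherapy) & !(out$radiotherapy %in% c(0, 1))
  if (any(bad_rt))
    stop(sprintf("radiotherapy outside {0,1}: value %s (sample %s)",
                 out$radiotherapy[bad_rt][1], out$sample_id[bad_rt][1]))
  for (cv in schema) {
    if (!cv$name %in% colnames(raw))
      stop("schema covariate absent from clinical table: ", cv$name)
    x <- blank(raw[[cv$name]])
    if (cv$kind == "continuous") {
      out[[cv$name]] <- {
        v <- suppressWarnings(as.numeric(x))
        bad <- !is.na(x) & is.na(v)
        if (any(bad))
          stop(sprintf("non-numeric value '%s' in continuous covariate '%s'", x[bad][1], cv$name))
        v
      }
    } else {
      unknown <- setdiff(unique(x[!is.na(x)]), cv$levels)
      if (length(unknown))
        stop(sprintf("unknown level(s) in covariate '%s': %s",
                     cv$name, paste(unknown, collapse = ", ")))
      out[[cv$name]] <- factor(x, levels = cv$levels)
    }
  }
  attr(out, "schema") <- schema
  out
}

#' Write an RS-call table
#'
#' One row per gene with the verdict (`is_rs`, `rs_type`, `direction`) and
#' the scenario A-D hazard ratios and p-values. Readable back with
#' [read_rs_table()].
#'
#' @param calls RS-call table from [discover_rs()] (or a compatible
#'   `data.frame`).
#' @param path Output path (tab-separated text).
#' @return Invisibly, the `data.frame` written.
#' @export
write_rs_table <- function(calls, path) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0) stop("no calls to write")
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Read back an RS-call table written by [write_rs_table()]
#' @param path Path to the tab-separated call table.
#' @return A `data.frame` of per-gene calls.
#' @export
read_rs_table <- function(path) {
  out <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("is_rs", "ambiguous", "direction_warning"), colnames(out)))
    out[[col]] <- as.logical(out[[col]])
  out
}

#' Write an expression matrix to tab-separated text
#' @param expr Numeric matrix, genes in rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clinical table to tab-separated text
#'
#' Missing cells are written as `NA`; [read_clinical()] restores them.
#' @param clin Clinical `data.frame` as returned by [read_clinical()] or
#'   [generate_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
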