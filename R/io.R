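# Readers and writers for the pipeline's tabular formats. All tables are
# plain CSV/TSV with documented headers; instrument exports (StepOne melt
# data, GeneMapper peak tables) are emulated by these column contracts.

table_schemas <- list(
  truth = list(cols = c(embryo_id = "character", sex = "character",
                        y_copies = "integer", x_copies = "integer",
                        chr18_copies = "integer", chr21_copies = "integer",
                        xx_male_translocation = "logical",
                        wga_failure = "logical"), sep = ","),
  melt = list(cols = c(embryo_id = "character", gene = "character",
                       temperature_c = "numeric", fluorescence = "numeric"),
              sep = ","),
  detections = list(cols = c(embryo_id = "character", gene = "character",
                             detected = "logical", tm_observed = "numeric",
                             qc_pass = "logical"), sep = ","),
  peaks = list(cols = c(embryo_id = "character", size_bp = "numeric",
                        height_rfu = "numeric"), sep = "\t"),
  ct = list(cols = c(embryo_id = "character", gene = "character",
                     input_ng = "numeric", ct = "numeric"), sep = ",")
)

coerce_column <- function(x, type, col) {
  suppress <- function(expr) withCallingHandlers(expr, warning = function(w)
    invokeRestart("muffleWarning"))
  out <- switch(type,
                character = as.character(x),
                numeric = suppress(as.numeric(x)),
                integer = suppress(as.integer(x)),
                logical = as.logical(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA" & x != "")
  if (length(bad)) {
    stop(sprintf("column '%s': cannot parse value '%s' at row %d",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read one of the pipeline's tables with schema validation
#'
#' Validates the header against the named schema, coerces column types with
#' row-numbered error messages, and accepts (with a warning) unknown extra
#' columns.
#'
#' @param path File path.
#' @param schema One of `"truth"`, `"melt"`, `"detections"`, `"peaks"`,
#'   `"ct"`.
#' @return A typed data frame.
#' @export
read_pgt_table <- function(path, schema) {
  if (!schema %in% names(table_schemas)) {
    stop("unknown schema '", schema, "'", call. = FALSE)
  }
  sch <- table_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sch$sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0) stop("empty table: ", path, call. = FALSE)
  missing <- setdiff(names(sch$cols), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), names(sch$cols))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  out <- raw[names(sch$cols)]
  for (col in names(sch$cols)) {
    out[[col]] <- coerce_column(raw[[col]], sch$cols[[col]], col)
  }
  out
}

#' @rdname read_pgt_table
#' @param x Data frame to write.
#' @export
write_pgt_table <- function(x, path, schema) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema '", schema, "'", call. = FALSE)
  missing <- setdiff(names(sch$cols), names(x))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(x[names(sch$cols)], path, sep = sch$sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convenience wrappers for the individual formats
#'
#' Long-format melt CSV (`embryo_id, gene, temperature_c, fluorescence`),
#' GeneMapper-style peak TSV (`embryo_id, size_bp, height_rfu`), Ct CSV
#' (`embryo_id, gene, input_ng, ct`), truth CSV, and melt-call detections
#' CSV.
#'
#' @param path File path.
#' @return A typed data frame.
#' @export
read_melt_table <- function(path) read_pgt_table(path, "melt")

#' @rdname read_melt_table
#' @export
read_peak_table <- function(path) read_pgt_table(path, "peaks")

#' @rdname read_melt_table
#' @export
read_ct_table <- function(path) read_pgt_table(path, "ct")

#' @rdname read_melt_table
#' @export
read_truth_table <- function(path) read_pgt_table(path, "truth")

#' @rdname read_melt_table
#' @export
read_detections_table <- function(path) read_pgt_table(path, "detections")
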