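## TSV dialect for count tables: UTF-8, tab-separated, header
## `sex dsred egfp body count`, lower-case categorical values
## (female/male, true/false, full/mosaic/none/na, wild/yellow/mosaic_yellow).
## Optional leading `# key: value` comment lines carry the design name and
## number of pooled crosses so that write -> read round-trips exactly.

EGFP_TSV <- c(full = "full", mosaic = "mosaic", none = "none",
              not_applicable = "na")
EGFP_FROM_TSV <- stats::setNames(names(EGFP_TSV), EGFP_TSV)

#' Read a phenotype count table from TSV
#'
#' Parses the package's count-table TSV dialect (see
#' \code{\link{write_count_table}}); rejects malformed rows with the
#' offending line number, unknown columns, negative or non-integer counts,
#' unknown phenotype labels and duplicate phenotype keys.
#'
#' @param path file path.
#' @return A \code{\link{count_table}}.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("read_count_table: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  design <- NA_character_
  n_crosses <- NA_integer_
  meta <- grepl("^#", lines)
  for (ln in lines[meta]) {
    if (grepl("^# design:", ln)) design <- trimws(sub("^# design:", "", ln))
    if (grepl("^# n_crosses:", ln)) n_crosses <- as.integer(trimws(sub("^# n_crosses:", "", ln)))
  }
  body_idx <- which(!meta & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("read_count_table: no header line in ", path)
  header_line <- body_idx[1L]
  header <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, CT_COLS))
    stop(sprintf("read_count_table: schema error, header must be '%s' (got '%s')",
                 paste(CT_COLS, collapse = "\t"), lines[header_line]))
  rows <- lapply(body_idx[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L)
      stop(sprintf("read_count_table: parse error at line %d: expected 5 fields, got %d", i, length(f)))
    if (!f[1L] %in% c("female", "male"))
      stop(sprintf("read_count_table: parse error at line %d: unknown sex '%s'", i, f[1L]))
    if (!f[2L] %in% c("true", "false"))
      stop(sprintf("read_count_table: parse error at line %d: dsred must be true/false, got '%s'", i, f[2L]))
    if (!f[3L] %in% names(EGFP_FROM_TSV))
      stop(sprintf("read_count_table: parse error at line %d: unknown egfp class '%s'", i, f[3L]))
    if (!f[4L] %in% BODY_CLASSES)
      stop(sprintf("read_count_table: parse error at line %d: unknown body class '%s'", i, f[4L]))
    cnt <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(cnt) || cnt < 0 || cnt != round(cnt))
      stop(sprintf("read_count_table: parse error at line %d: count must be a non-negative integer, got '%s'", i, f[5L]))
    data.frame(sex = f[1L], dsred = f[2L] == "true",
               egfp = unname(EGFP_FROM_TSV[f[3L]]), body = f[4L],
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else data.frame()
  tryCatch(count_table(df, design = design, n_crosses = n_crosses),
           error = function(e) stop("read_count_table: schema error: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a phenotype count table to TSV
#'
#' Writes the canonical tab-separated representation (metadata comment
#' lines, header, one row per phenotype class). The round-trip property
#' \code{read_count_table(write_count_table(t)) == t} holds exactly.
#'
#' @param t a \code{\link{count_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(t, path) {
  ct_check(t)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.na(attr(t, "design"))) writeLines(paste0("# design: ", attr(t, "design")), con)
  if (!is.na(attr(t, "n_crosses"))) writeLines(paste0("# n_crosses: ", attr(t, "n_crosses")), con)
  writeLines(paste(CT_COLS, collapse = "\t"), con)
  if (nrow(t) > 0L) {
    out <- paste(t$sex, ifelse(t$dsred, "true", "false"),
                 unname(EGFP_TSV[t$egfp]), t$body, t$count, sep = "\t")
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a flat key-value run configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and blank
#' lines ignored. Keys mirror the CLI flags with underscores (e.g.
#' \code{c_f}, \code{n_crosses}, \code{seed}). CLI flags override file
#' values.
#'
#' @param path file path.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L)
      stop("read_run_config: malformed line ", i, ": ", lines[i])
    out[[m[2L]]] <- trimws(m[3L])
  }
  out
}
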