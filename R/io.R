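#' Read a melt-fluorescence table
#'
#' Parses the two canonical plain-text dialects for raw melt exports.
#' The *wide* dialect has a first column named `temperature` and one
#' column per well; the *long* dialect has columns `sample_id`,
#' `temperature`, `rfu`. The field separator (comma or tab) is detected
#' from the header line; the decimal separator is always `"."`,
#' never locale-dependent. Instrument exports (spreadsheets from
#' real-time PCR software) are supported through an "export to delimited
#' text first" contract: save the temperature/RFU block as CSV or TSV in
#' the wide dialect and read it here.
#'
#' Sample order follows the file: column order in the wide dialect,
#' first appearance in the long dialect. The temperature grid is stored
#' exactly as read; uniform spacing is *not* assumed at parse time
#' (downstream operations check it where they need it). Duplicated or
#' non-increasing temperature rows are an error, never silently fixed.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"auto"` (default), `"wide"` or `"long"`.
#' @return A tibble with columns `sample_id`, `temperature`, `rfu`,
#'   rows ordered by sample (file order) then temperature.
#' @seealso [write_melt_table()], [read_sample_sheet()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("temperature,A1,A2", "65.0,10,11", "65.1,9,10.5"), path)
#' read_melt_table(path)
read_melt_table <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("melt table needs a header and at least one data row: ", path,
         call. = FALSE)
  }
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- trimws(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]])
  if (dialect == "auto") {
    low <- tolower(header)
    dialect <- if (identical(sort(low), sort(c("sample_id", "temperature", "rfu")))) {
      "long"
    } else if (low[[1L]] == "temperature" && length(header) >= 2L) {
      "wide"
    } else {
      stop("cannot determine dialect from header: ",
           paste(header, collapse = ", "), call. = FALSE)
    }
  }
  cells <- lapply(lines[-1L], function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1L]]))
  n_col <- length(header)
  bad <- which(vapply(cells, length, 1L) != n_col)
  if (length(bad)) {
    stop("row ", bad[[1L]] + 1L, " has ", length(cells[[bad[[1L]]]]),
         " fields, expected ", n_col, call. = FALSE)
  }
  num_cell <- function(x, row, col) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) && !(tolower(x) %in% c("na", "nan"))) {
      stop("non-numeric value ", dQuote(x), " at data row ", row,
           ", column ", dQuote(header[[col]]), call. = FALSE)
    }
    v
  }

  if (dialect == "wide") {
    if (tolower(header[[1L]]) != "temperature") {
      stop("wide dialect requires first column 'temperature', got ",
           dQuote(header[[1L]]), call. = FALSE)
    }
    mat <- matrix(NA_real_, nrow = length(cells), ncol = n_col)
    for (i in seq_along(cells)) {
      for (j in seq_len(n_col)) mat[i, j] <- num_cell(cells[[i]][[j]], i, j)
    }
    temps <- mat[, 1L]
    dup <- which(duplicated(temps))
    if (length(dup)) {
      stop("duplicate temperature ", temps[[dup[[1L]]]], " at data row ",
           dup[[1L]], call. = FALSE)
    }
    if (any(diff(temps) <= 0)) {
      stop("temperatures not strictly increasing at data row ",
           which(diff(temps) <= 0)[[1L]] + 1L, call. = FALSE)
    }
    ids <- header[-1L]
    if (anyDuplicated(ids)) {
      stop("duplicate sample column: ", ids[duplicated(ids)][[1L]], call. = FALSE)
    }
    out <- tibble(
      sample_id = rep(ids, each = length(temps)),
      temperature = rep(temps, times = length(ids)),
      rfu = as.vector(mat[, -1L, drop = FALSE])
    )
  } else {
    idx <- match(c("sample_id", "temperature", "rfu"), tolower(header))
    rows <- lapply(seq_along(cells), function(i) {
      c0 <- cells[[i]]
      tibble(
        sample_id = c0[[idx[[1L]]]],
        temperature = num_cell(c0[[idx[[2L]]]], i, idx[[2L]]),
        rfu = num_cell(c0[[idx[[3L]]]], i, idx[[3L]])
      )
    })
    out <- bind_rows(rows)
    ids <- unique(out$sample_id)
    out <- out[order(match(out$sample_id, ids), out$temperature), ]
  }
  validate_melt_data(out)
  out
}

#' Validate a long melt-data tibble
#'
#' Checks the invariants every melt dataset must satisfy: at least two
#' temperature points, finite RFU values, a shared strictly increasing
#' temperature grid, and one RFU value per sample and temperature.
#'
#' @param data A long tibble with `sample_id`, `temperature`, `rfu` (or
#'   another value column named by `value`).
#' @param value Name of the value column (default `"rfu"`).
#' @return Invisibly `TRUE`; errors describe the first violation.
#' @export
validate_melt_data <- function(data, value = "rfu") {
  need <- c("sample_id", "temperature", value)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("melt data is empty", call. = FALSE)
  if (!all(is.finite(data$temperature))) {
    stop("non-finite temperature values", call. = FALSE)
  }
  if (!all(is.finite(data[[value]]))) {
    stop("non-finite ", value, " values", call. = FALSE)
  }
  grids <- split(data$temperature, data$sample_id)
  ref <- grids[[1L]]
  if (length(ref) < 2L) stop("fewer than 2 temperature points", call. = FALSE)
  if (any(diff(ref) <= 0)) {
    stop("temperatures not strictly increasing within sample ",
         names(grids)[[1L]], call. = FALSE)
  }
  same <- vapply(grids, function(g) length(g) == length(ref) && all(g == ref),
                 logical(1L))
  if (!all(same)) {
    stop("samples on differing temperature grids: ",
         paste(names(grids)[!same][1:min(3L, sum(!same))], collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a melt table in the canonical wide dialect
#'
#' Numbers are written with 6 significant digits, so a write/read
#' round-trip reproduces the dataset to that precision. Writing an
#' empty dataset is refused.
#'
#' @param data Long tibble (`sample_id`, `temperature`, value column).
#' @param path Output file path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @param value Name of the value column to write (default `"rfu"`,
#'   use `"dneg"` or `"delta"` for processed curves).
#' @return Invisibly `path`.
#' @export
write_melt_table <- function(data, path, value = "rfu") {
  if (is.null(data) || nrow(data) == 0L) {
    stop("refusing to write an empty melt dataset", call. = FALSE)
  }
  validate_melt_data(data, value = value)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ids <- unique(data$sample_id)
  temps <- unique(data$temperature)
  wide <- matrix(NA_real_, nrow = length(temps), ncol = length(ids))
  for (k in seq_along(ids)) {
    sub <- data[data$sample_id == ids[[k]], ]
    wide[, k] <- sub[[value]][match(temps, sub$temperature)]
  }
  fmt <- function(x) sprintf("%.6g", x)
  lines <- c(
    paste(c("temperature", ids), collapse = sep),
    vapply(seq_along(temps), function(i) {
      paste(c(fmt(temps[[i]]), fmt(wide[i, ])), collapse = sep)
    }, character(1L))
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet assigns per-well metadata: taxon/haplotype `label`,
#' `replicate_group` (wells averaged together), and `role` (`reference`
#' wells build the curve library, `unknown` wells get classified).
#'
#' @param path Delimited text file with columns `sample_id`, `label`,
#'   `replicate_group`, `role`.
#' @return A tibble with those four character columns (possibly empty).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sample sheet: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- tolower(trimws(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]))
  need <- c("sample_id", "label", "replicate_group", "role")
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(lines) == 1L) {
    return(tibble(sample_id = character(), label = character(),
                  replicate_group = character(), role = character()))
  }
  cells <- lapply(lines[-1L], function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1L]]))
  get <- function(row, col) {
    j <- match(col, header)
    if (j <= length(row)) row[[j]] else NA_character_
  }
  out <- bind_rows(lapply(cells, function(r) {
    tibble(sample_id = get(r, "sample_id"), label = get(r, "label"),
           replicate_group = get(r, "replicate_group"), role = get(r, "role"))
  }))
  bad <- !out$role %in% c("reference", "unknown")
  if (any(bad)) {
    stop("invalid role(s): ", paste(unique(out$role[bad]), collapse = ", "),
         " (must be 'reference' or 'unknown')", call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in sheet: ",
         out$sample_id[duplicated(out$sample_id)][[1L]], call. = FALSE)
  }
  out
}

#' Attach sample-sheet metadata to melt data
#'
#' Joins `label`, `replicate_group` and `role` onto a long melt tibble.
#' Sheet rows whose `sample_id` does not occur in the data are an error
#' (a mislabeled plate should fail loudly, not silently drop wells).
#'
#' @param data Long melt tibble.
#' @param sheet Tibble from [read_sample_sheet()].
#' @return `data` with the three metadata columns added.
#' @export
apply_sample_sheet <- function(data, sheet) {
  orphans <- setdiff(sheet$sample_id, unique(data$sample_id))
  if (length(orphans)) {
    stop("sample sheet refers to unknown sample_id(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  data <- data[setdiff(names(data), c("label", "replicate_group", "role"))]
  left_join(data, sheet, by = "sample_id")
}
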