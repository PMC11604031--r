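#' Read curve data from delimited text
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`wide-csv`}{one row per curve; optional first column `label` with
#'     the group identifier; optional header row whose numeric entries are
#'     the grid times (a leading `label` field marks the label column).
#'     Without a time header the grid defaults to indices `1..p`.}
#'   \item{`long-csv`}{columns `curve_id, time, value` and optionally
#'     `label`; curves may be irregularly sampled and are projected onto a
#'     common grid with [smooth_to_common_grid()].}
#'   \item{`ucr-text`}{UCR-archive style: whitespace- or comma-separated,
#'     first column an integer class label, remaining columns the curve
#'     values on an implicit `1..p` grid.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"wide-csv"`, `"long-csv"`, `"ucr-text"`.
#' @param grid optional [grid_domain()] overriding the inferred grid (for
#'   `long-csv` this is the smoothing target).
#' @param bandwidth smoothing bandwidth for `long-csv` (see
#'   [smooth_to_common_grid()]).
#' @return A single [curve_set()] when the file carries no labels, otherwise
#'   a named list of [curve_set()]s, one per label (sorted).
#' @export
read_curves <- function(path, dialect = c("wide-csv", "long-csv", "ucr-text"),
                        grid = NULL, bandwidth = "auto") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("file '%s' does not exist", path))
  }
  switch(dialect,
    "wide-csv" = read_wide_csv(path, grid),
    "long-csv" = read_long_csv(path, grid, bandwidth),
    "ucr-text" = read_ucr_text(path, grid)
  )
}

index_grid <- function(p) grid_domain(p, t_min = 1, t_max = p + 1)

split_by_label <- function(values, labels, grid) {
  if (is.null(labels)) {
    return(curve_set(values, grid))
  }
  out <- lapply(sort(unique(labels)), function(lb) {
    curve_set(values[labels == lb, , drop = FALSE], grid, label = lb)
  })
  names(out) <- sort(unique(labels))
  out
}

parse_numeric_cells <- function(rows, path, offset = 0L) {
  width <- length(rows[[1]])
  mat <- matrix(NA_real_, length(rows), width)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != width) {
      stop_invalid_input(sprintf(
        "ragged row in '%s' at line %d (%d fields, expected %d)",
        path, i + offset, length(rows[[i]]), width
      ))
    }
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      stop_invalid_input(sprintf(
        "non-numeric cell in '%s' at line %d", path, i + offset
      ))
    }
    mat[i, ] <- v
  }
  mat
}

read_wide_csv <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid_input(sprintf("'%s' is empty", path))
  cells <- strsplit(lines, ",")
  cells <- lapply(cells, trimws)
  first <- cells[[1L]]
  # header row: any non-numeric token (e.g. "label" or "t1") in line 1
  header <- anyNA(suppressWarnings(as.numeric(first)))
  has_label <- FALSE
  times <- NULL
  if (header) {
    toks <- first
    if (identical(tolower(toks[1L]), "label")) {
      has_label <- TRUE
      toks <- toks[-1L]
    }
    tv <- suppressWarnings(as.numeric(toks))
    if (!anyNA(tv)) times <- tv
    cells <- cells[-1L]
    if (length(cells) == 0L) {
      stop_invalid_input(sprintf("'%s' has a header but no data rows", path))
    }
  }
  labels <- NULL
  if (has_label) {
    labels <- vapply(cells, function(r) r[1L], "")
    cells <- lapply(cells, function(r) r[-1L])
  }
  values <- parse_numeric_cells(cells, path, offset = as.integer(header))
  p <- ncol(values)
  if (is.null(grid)) {
    grid <- if (!is.null(times)) {
      grid_domain(p,
        t_min = times[1L],
        t_max = times[p] + (times[p] - times[1L]) / max(p - 1L, 1L),
        points = times
      )
    } else {
      index_grid(p)
    }
  }
  split_by_label(values, labels, grid)
}

read_long_csv <- function(path, grid = NULL, bandwidth = "auto") {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_invalid_input(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  need <- c("curve_id", "time", "value")
  if (!all(need %in% names(df))) {
    stop_invalid_input("long-csv requires columns curve_id, time, value (label optional)")
  }
  if (!is.numeric(df$time) || !is.numeric(df$value) || anyNA(df$time) || anyNA(df$value)) {
    stop_invalid_input(sprintf("non-numeric time/value cells in '%s'", path))
  }
  has_label <- "label" %in% names(df)
  if (is.null(grid)) {
    per_curve <- table(df$curve_id)
    grid <- grid_domain(
      max(2L, as.integer(stats::median(per_curve))),
      t_min = min(df$time), t_max = max(df$time) + 1e-9
    )
  }
  groups <- if (has_label) sort(unique(df$label)) else NA
  out <- lapply(groups, function(lb) {
    sub <- if (has_label) df[df$label == lb, , drop = FALSE] else df
    raw <- lapply(split(sub, sub$curve_id), function(d) {
      list(times = d$time, values = d$value)
    })
    smooth_to_common_grid(raw, grid,
      bandwidth = bandwidth,
      label = if (has_label) lb else NULL
    )
  })
  if (!has_label) {
    return(out[[1L]])
  }
  names(out) <- groups
  out
}

read_ucr_text <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid_input(sprintf("'%s' is empty", path))
  sep <- if (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
  cells <- lapply(strsplit(trimws(lines), sep), trimws)
  mat <- parse_numeric_cells(cells, path)
  labels <- as.integer(mat[, 1L])
  values <- mat[, -1L, drop = FALSE]
  if (is.null(grid)) grid <- index_grid(ncol(values))
  split_by_label(values, labels, grid)
}

#' Write a curve set (or list of curve sets) as wide CSV
#'
#' Header row is `label, t1, t2, ...` (the grid times); each data row is the
#' curve's label followed by its values. The output round-trips through
#' [read_curves()] with dialect `"wide-csv"`.
#'
#' @param curves a [curve_set()] or a list of them sharing one grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "curve_set")) curves <- list(curves)
  grid <- curves[[1L]]$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    paste(c("label", format(grid$points, digits = 17, trim = TRUE)),
      collapse = ","
    ),
    con
  )
  for (cs in curves) {
    lb <- if (is.null(cs$label)) "0" else as.character(cs$label)
    for (i in seq_len(nrow(cs$values))) {
      writeLines(
        paste(c(lb, format(cs$values[i, ], digits = 17, trim = TRUE)),
          collapse = ","
        ),
        con
      )
    }
  }
  invisible(path)
}
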