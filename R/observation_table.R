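#' Declare an observation table
#'
#' Wraps a long-format data frame and declares which columns play which
#' role: one (optional) response, numeric fixed-effect covariates, and one
#' or more grouping-factor ID columns (e.g. subject, item). Roles are
#' declared explicitly, never inferred. Grouping columns are coerced to
#' character; downstream resizing appends fresh IDs to them.
#'
#' A table without a response column (\code{response = NULL}) is a
#' design-only table: it can feed \code{\link{simulate_response}} and the
#' power engine, which generate the response, but not the fitting
#' functions directly.
#'
#' @param data a data frame in long format, one row per observation.
#' @param response name of the response column, or \code{NULL} for a
#'   design-only table. Must be numeric if present.
#' @param covariates character vector of numeric covariate columns
#'   (assumed already coded/centered as intended).
#' @param grouping character vector of grouping-factor ID columns; each
#'   must have at least 2 distinct levels.
#' @return the data with class \code{obs_table} and a \code{roles}
#'   attribute.
#' @examples
#' d <- data.frame(y = rnorm(8), x = rnorm(8),
#'                 subj = rep(c("a", "b"), each = 4),
#'                 item = rep(c("i1", "i2", "i3", "i4"), 2))
#' tab <- observation_table(d, response = "y", covariates = "x",
#'                          grouping = c("subj", "item"))
#' roles(tab)
#' @export
observation_table <- function(data, response = NULL,
                              covariates = character(),
                              grouping = character()) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  response <- if (length(response)) as.character(response)[1L] else NULL
  covariates <- as.character(covariates)
  grouping <- as.character(grouping)

  used <- c(response, covariates, grouping)
  absent <- setdiff(used, names(data))
  if (length(absent)) {
    stop("column(s) not found in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (length(used) && anyNA(data[, used, drop = FALSE])) {
    bad <- used[vapply(data[, used, drop = FALSE], anyNA, logical(1))]
    stop("missing values in declared column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(response) && !is.numeric(data[[response]])) {
    stop("response column '", response, "' must be numeric", call. = FALSE)
  }
  for (v in covariates) {
    if (!is.numeric(data[[v]])) {
      stop("covariate '", v, "' must be numeric", call. = FALSE)
    }
  }
  for (g in grouping) {
    data[[g]] <- as.character(data[[g]])
    if (length(unique(data[[g]])) < 2L) {
      stop("grouping factor '", g, "' has fewer than 2 levels",
           call. = FALSE)
    }
  }
  structure(data,
            roles = list(response = response, covariates = covariates,
                         grouping = grouping),
            class = c("obs_table", "data.frame"))
}

#' Column roles of an observation table
#'
#' @param x an \code{obs_table}.
#' @return a list with elements \code{response}, \code{covariates} and
#'   \code{grouping}.
#' @export
roles <- function(x) {
  r <- attr(x, "roles")
  if (is.null(r)) stop("not an observation table (no roles attribute)",
                       call. = FALSE)
  r
}

#' Read an observation table from CSV or TSV
#'
#' Reads a delimited text file with a header row and declares column
#' roles. Rows with missing values in any declared column are rejected at
#' load time (dropped with a warning).
#'
#' @param path file path; delimiter is inferred from the extension
#'   (\code{.tsv}/\code{.txt} = tab, otherwise comma) unless \code{sep}
#'   is given.
#' @param sep field separator, overriding the extension-based guess.
#' @inheritParams observation_table
#' @return an \code{obs_table}.
#' @export
read_observation_table <- function(path, response = NULL,
                                   covariates = character(),
                                   grouping = character(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  used <- c(response, covariates, grouping)
  absent <- setdiff(used, names(df))
  if (length(absent)) {
    stop("file ", path, " lacks declared column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(df[, used, drop = FALSE])
  if (!all(keep)) {
    warning("rejected ", sum(!keep), " row(s) with missing values in ",
            "declared columns", call. = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  observation_table(df, response = response, covariates = covariates,
                    grouping = grouping)
}

#' @export
print.obs_table <- function(x, ...) {
  r <- roles(x)
  cat("Observation table:", nrow(x), "rows\n")
  cat("  response :", if (is.null(r$response)) "<none (design only)>"
      else r$response, "\n")
  cat("  covariates:", if (length(r$covariates))
      paste(r$covariates, collapse = ", ") else "<none>", "\n")
  for (g in r$grouping) {
    cat("  grouping  :", g, "(", length(unique(x[[g]])), "levels )\n")
  }
  NextMethod()
  invisible(x)
}

# replace/insert the response column, preserving roles
set_response <- function(data, values, name = NULL) {
  r <- roles(data)
  if (is.null(name)) name <- if (is.null(r$response)) ".sim_response" else r$response
  df <- as.data.frame(data)
  df[[name]] <- values
  observation_table(df, response = name, covariates = r$covariates,
                    grouping = r$grouping)
}
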