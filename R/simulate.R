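#' Simulate a response vector from a mixed model
#'
#' Step 1 of the simulate--refit--count loop. For a Gaussian model the
#' response is \eqn{y = X\beta + \sum_g Z_g b_g + \epsilon}, with one
#' random-intercept draw \eqn{b_g \sim N(0, \sigma^2_g)} per level of
#' each grouping factor and residual noise per row. For a binomial model
#' \eqn{y \sim Bernoulli(logit^{-1}(X\beta + \sum_g Z_g b_g))}.
#' Random-effect draws are per level, not per row, and are redrawn on
#' every call: each simulation repetition represents new participants
#' and items.
#'
#' Draw order is fixed (grouping factors in spec order, then the
#' row-level noise), so an identical seed yields an identical vector.
#'
#' @param model a \code{\link{mixed_model}}.
#' @param data an \code{obs_table} (response column, if any, is ignored).
#' @param seed integer seed; \code{NULL} continues the current RNG
#'   stream.
#' @return numeric response vector of length \code{nrow(data)}.
#' @export
simulate_response <- function(model, data, seed = NULL) {
  if (!inherits(model, "mixed_model")) stop("`model` must be a mixed_model",
                                            call. = FALSE)
  des <- build_design(data, model$spec)
  eta <- drop(des$X %*% model$beta)
  if (!is.null(seed)) set.seed(seed)
  for (g in model$spec$grouping) {
    b <- stats::rnorm(ncol(des$Z[[g]]), 0, sqrt(model$variances[[g]]))
    eta <- eta + as.vector(des$Z[[g]] %*% b)
  }
  n <- length(eta)
  if (model$spec$family == "gaussian") {
    eta + stats::rnorm(n, 0, sqrt(model$residual_variance))
  } else {
    stats::rbinom(n, 1L, stats::plogis(eta))
  }
}

#' Resize a dataset along a grouping factor
#'
#' Changes the number of levels of one grouping factor (e.g. subjects)
#' while preserving the design's covariate structure, producing the
#' "requested number of observations" for a power step. Shrinking keeps
#' a uniform random subset of existing levels with all their rows.
#' Growing clones whole level blocks -- covariates intact, fresh unique
#' IDs -- cycling through the source levels in a shuffled order until the
#' target count is reached, so no source level is over-represented.
#' An equal target returns the data structurally unchanged.
#'
#' Any response values carried along are placeholders: power scans
#' re-simulate the response after resizing. Covariate columns are never
#' recentered here; recentering after a resize is the caller's explicit
#' choice.
#'
#' @param data an \code{obs_table}.
#' @param factor name of a declared grouping factor.
#' @param target_level_count desired number of levels (>= 2).
#' @param seed integer seed driving the level sampling / cloning order.
#' @return an \code{obs_table} with \code{target_level_count} levels of
#'   \code{factor} and a \code{provenance} attribute describing the
#'   resize.
#' @export
resize_by_factor <- function(data, factor, target_level_count,
                             seed = NULL) {
  r <- roles(data)
  if (!factor %in% r$grouping) {
    stop("'", factor, "' is not a declared grouping factor", call. = FALSE)
  }
  target <- as.integer(target_level_count)
  if (is.na(target) || target < 2L) {
    stop("target_level_count must be an integer >= 2", call. = FALSE)
  }
  ids <- as.character(data[[factor]])
  lev <- unique(ids)
  k <- length(lev)
  prov <- list(factor = factor, from = k, to = target, seed = seed)

  if (target == k) {
    attr(data, "provenance") <- prov
    return(data)
  }
  if (!is.null(seed)) set.seed(seed)
  if (target < k) {
    keep <- sample(lev, target)
    out <- as.data.frame(data)[ids %in% keep, , drop = FALSE]
  } else {
    n_new <- target - k
    src <- sample(lev)  # shuffled cycling order over source levels
    existing <- lev
    add <- vector("list", n_new)
    df <- as.data.frame(data)
    for (i in seq_len(n_new)) {
      s <- src[((i - 1L) %% k) + 1L]
      blk <- df[ids == s, , drop = FALSE]
      nid <- sprintf("%s_new_%d", factor, i)
      while (nid %in% existing) nid <- paste0(nid, "_")
      existing <- c(existing, nid)
      blk[[factor]] <- nid
      add[[i]] <- blk
    }
    out <- rbind(df, do.call(rbind, add))
  }
  rownames(out) <- NULL
  out <- observation_table(out, response = r$response,
                           covariates = r$covariates,
                           grouping = r$grouping)
  attr(out, "provenance") <- prov
  out
}

#' Write a simulated dataset with its provenance
#'
#' Writes the table to CSV and, when present, its provenance (source
#' factor, level counts, seed) to a JSON sidecar, for auditing.
#'
#' @param data an \code{obs_table}.
#' @param path CSV output path; the sidecar is \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  prov <- attr(data, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
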