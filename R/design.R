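#' Build the fixed and random design matrices
#'
#' Constructs the fixed-effect design matrix (one column per term;
#' interaction columns are elementwise products of their parent columns)
#' and one sparse indicator matrix per grouping factor (one column per
#' level, one 1 per row). Level ordering is deterministic
#' first-appearance order.
#'
#' @param data an \code{obs_table} (or plain data frame) holding the
#'   spec's columns.
#' @param spec a \code{model_spec}.
#' @return a list with \code{X} (dense numeric matrix, n x terms) and
#'   \code{Z} (named list of \code{\link[Matrix]{sparseMatrix}} indicator
#'   matrices).
#' @export
build_design <- function(data, spec) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec",
                                          call. = FALSE)
  n <- nrow(data)
  X <- matrix(1, nrow = n, ncol = length(spec$terms),
              dimnames = list(NULL, spec$terms))
  for (tm in spec$fixed_effects) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    for (p in parents) {
      if (!p %in% names(data)) {
        stop("model term '", tm, "' needs column '", p,
             "', which is missing from the data", call. = FALSE)
      }
      if (!is.numeric(data[[p]])) {
        stop("column '", p, "' must be numeric (code categorical ",
             "predictors before modelling)", call. = FALSE)
      }
    }
    X[, tm] <- Reduce(`*`, lapply(parents, function(p) data[[p]]))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("fixed design is rank deficient (constant covariate together ",
         "with an intercept, or aliased terms)", call. = FALSE)
  }
  Z <- vector("list", length(spec$grouping))
  names(Z) <- spec$grouping
  for (g in spec$grouping) {
    if (!g %in% names(data)) {
      stop("grouping factor '", g, "' is missing from the data",
           call. = FALSE)
    }
    ids <- as.character(data[[g]])
    lev <- unique(ids)
    Z[[g]] <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, lev),
                                   x = 1, dims = c(n, length(lev)),
                                   dimnames = list(NULL, lev))
  }
  list(X = X, Z = Z)
}
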