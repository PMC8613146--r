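#' Specify a mixed model's structure
#'
#' A model specification lists the fixed-effect terms (main effects and
#' pairwise interactions written \code{"a:b"}; the intercept is implicit
#' and always first), the grouping factors that each receive a random
#' intercept, and the response family. Random slopes are out of scope:
#' the random structure is intercepts only.
#'
#' @param fixed_effects character vector of non-intercept fixed-effect
#'   term labels, e.g. \code{c("x", "z", "x:z")}. Interaction columns are
#'   elementwise products of their parent columns.
#' @param grouping character vector of distinct grouping-factor names,
#'   each contributing a random intercept.
#' @param family \code{"gaussian"} (identity link, REML) or
#'   \code{"binomial"} (logit link, Laplace ML).
#' @return a \code{model_spec} object.
#' @examples
#' model_spec(c("NativeLanguage", "CenteredFrequency",
#'              "NativeLanguage:CenteredFrequency"),
#'            grouping = c("Subject", "Word"), family = "binomial")
#' @export
model_spec <- function(fixed_effects = character(), grouping = character(),
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  fixed_effects <- as.character(fixed_effects)
  grouping <- as.character(grouping)
  if ("(Intercept)" %in% fixed_effects) {
    stop("the intercept is implicit; do not list it in `fixed_effects`",
         call. = FALSE)
  }
  if (anyDuplicated(fixed_effects)) {
    stop("duplicated fixed-effect terms", call. = FALSE)
  }
  if (anyDuplicated(grouping)) {
    stop("grouping factors must be distinct names", call. = FALSE)
  }
  structure(list(terms = c("(Intercept)", fixed_effects),
                 fixed_effects = fixed_effects,
                 grouping = grouping,
                 family = family),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec (", x$family, ")\n", sep = "")
  cat("  fixed :", paste(x$terms, collapse = " + "), "\n")
  if (length(x$grouping)) {
    cat("  random:", paste(sprintf("(1 | %s)", x$grouping), collapse = " + "),
        "\n")
  } else cat("  random: <none>\n")
  invisible(x)
}

# model formula for a spec; response name supplied by the data roles
spec_formula <- function(spec, response) {
  rhs <- c(if (length(spec$fixed_effects))
             paste0("`", gsub(":", "`:`", spec$fixed_effects, fixed = TRUE), "`")
           else "1",
           sprintf("(1 | `%s`)", spec$grouping))
  stats::as.formula(paste0("`", response, "` ~ ", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

#' Construct a fully specified mixed model
#'
#' Bundles a \code{\link{model_spec}} with numeric generative parameters:
#' fixed-effect coefficients on the link scale, one random-intercept
#' variance per grouping factor, and (Gaussian only) a residual variance.
#' The resulting object drives \code{\link{simulate_response}} and the
#' power engine without any fitting.
#'
#' @param spec a \code{model_spec}.
#' @param beta numeric coefficient vector aligned to the spec's terms
#'   (intercept first).
#' @param variances random-intercept variances, one per grouping factor.
#'   A named vector is matched by name (recommended); an unnamed vector is
#'   taken positionally in spec order, with a warning.
#' @param residual_variance Gaussian residual variance (>= 0); must be
#'   \code{NULL} for binomial models.
#' @return a \code{mixed_model} object.
#' @export
mixed_model <- function(spec, beta, variances = numeric(),
                        residual_variance = NULL) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec",
                                          call. = FALSE)
  beta <- as.numeric(beta)
  if (length(beta) != length(spec$terms)) {
    stop("`beta` must have length ", length(spec$terms),
         " (intercept + ", length(spec$fixed_effects),
         " fixed-effect terms), got ", length(beta), call. = FALSE)
  }
  names(beta) <- spec$terms

  variances <- unlist(variances)
  if (length(variances) != length(spec$grouping)) {
    stop("need one variance per grouping factor (",
         length(spec$grouping), "), got ", length(variances), call. = FALSE)
  }
  if (length(variances)) {
    if (is.null(names(variances)) || !any(nzchar(names(variances)))) {
      warning("unnamed random-intercept variances taken positionally as: ",
              paste(spec$grouping, collapse = ", "), call. = FALSE)
      names(variances) <- spec$grouping
    } else if (!setequal(names(variances), spec$grouping)) {
      stop("variance names must match grouping factors: ",
           paste(spec$grouping, collapse = ", "), call. = FALSE)
    }
    variances <- variances[spec$grouping]
    if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  }

  if (spec$family == "gaussian") {
    if (is.null(residual_variance)) {
      stop("Gaussian models need a residual_variance", call. = FALSE)
    }
    residual_variance <- as.numeric(residual_variance)[1L]
    if (residual_variance < 0) stop("residual_variance must be >= 0",
                                    call. = FALSE)
  } else if (!is.null(residual_variance)) {
    stop("binomial models have no residual_variance", call. = FALSE)
  }

  structure(list(spec = spec, beta = beta, variances = variances,
                 residual_variance = residual_variance),
            class = "mixed_model")
}

#' @export
print.mixed_model <- function(x, ...) {
  cat("Mixed model (", x$spec$family, ")\n", sep = "")
  cat("Fixed-effect coefficients:\n")
  print(x$beta)
  if (length(x$variances)) {
    cat("Random-intercept variances:\n")
    print(x$variances)
  }
  if (!is.null(x$residual_variance)) {
    cat("Residual variance:", x$residual_variance, "\n")
  }
  invisible(x)
}

#' Replace a model's coefficient vector
#'
#' Returns a copy of the model with the fixed-effect coefficients
#' replaced, leaving variances, family and spec untouched. This is how a
#' smallest effect size of interest (SESOI) is injected before
#' simulation: supply the full-length vector including the intercept,
#' e.g. all pilot-estimate coefficients shrunk by 15\% with the intercept
#' kept.
#'
#' @param model a \code{mixed_model}.
#' @param beta full-length replacement coefficient vector (including the
#'   intercept).
#' @return a new \code{mixed_model}.
#' @export
override_coefficients <- function(model, beta) {
  if (!inherits(model, "mixed_model")) stop("`model` must be a mixed_model",
                                            call. = FALSE)
  beta <- as.numeric(beta)
  if (length(beta) != length(model$beta)) {
    stop("override vector must have length ", length(model$beta),
         " (including the intercept), got ", length(beta), call. = FALSE)
  }
  model$beta <- stats::setNames(beta, names(model$beta))
  model
}

#' Build an artificial mixed model from chosen parameters
#'
#' Wraps user-chosen coefficients and variance components into a
#' generative model with no fitting involved, for power analysis from
#' scratch when no pilot data exist. The reported coefficients equal the
#' inputs exactly.
#'
#' @inheritParams mixed_model
#' @param family response family, overriding the spec's if given.
#' @return a \code{mixed_model}.
#' @seealso \code{\link{make_lexdec_model}} for the built-in worked
#'   example.
#' @export
make_artificial_model <- function(spec, beta, variances,
                                  residual_variance = NULL,
                                  family = NULL) {
  if (!is.null(family)) {
    spec <- model_spec(spec$fixed_effects, spec$grouping, family = family)
  }
  mixed_model(spec, beta, variances, residual_variance)
}
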