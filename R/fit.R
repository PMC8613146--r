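#' Significance rule for Wald statistics
#'
#' An effect counts as significant when the absolute Wald statistic
#' (t value for Gaussian fits, z value for binomial fits) strictly
#' exceeds its critical value. A scalar applies one threshold to all
#' effects; a named vector sets a different criterion per effect.
#' Conventional choices: 2 for Gaussian t values and 1.96 for binomial z
#' values, both reflecting an alpha level of about 5\%.
#'
#' @param critical positive threshold(s) on the absolute Wald statistic;
#'   scalar, or a (preferably named) vector with one entry per effect.
#' @return a \code{sig_rule} object.
#' @export
significance_rule <- function(critical = 2) {
  critical <- unlist(critical)
  if (!length(critical) || !is.numeric(critical) || any(critical <= 0)) {
    stop("critical values must be positive numbers", call. = FALSE)
  }
  structure(list(critical = critical), class = "sig_rule")
}

default_rule <- function(family) {
  significance_rule(if (family == "binomial") 1.96 else 2)
}

# expand a rule to a named per-effect threshold vector
resolve_rule <- function(rule, effects) {
  if (!inherits(rule, "sig_rule")) rule <- significance_rule(rule)
  crit <- rule$critical
  if (length(crit) == 1L && is.null(names(crit))) {
    return(stats::setNames(rep(crit, length(effects)), effects))
  }
  if (!is.null(names(crit)) && all(nzchar(names(crit)))) {
    absent <- setdiff(effects, names(crit))
    if (length(absent)) {
      stop("significance rule does not cover effect(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    return(crit[effects])
  }
  if (length(crit) != length(effects)) {
    stop("significance rule has ", length(crit), " thresholds for ",
         length(effects), " effects", call. = FALSE)
  }
  stats::setNames(crit, effects)
}

new_fit_result <- function(spec, status, messages = character(),
                           model = NULL, std_errors = NULL, wald = NULL,
                           objective = NA_real_, nobs = NA_integer_,
                           fit = NULL) {
  nt <- length(spec$terms)
  if (is.null(std_errors)) std_errors <- stats::setNames(rep(NA_real_, nt),
                                                         spec$terms)
  if (is.null(wald)) wald <- stats::setNames(rep(NA_real_, nt), spec$terms)
  structure(list(model = model, std_errors = std_errors, wald = wald,
                 objective = objective, status = status,
                 messages = messages, nobs = nobs, fit = fit),
            class = "cp_fit")
}

collect_conditions <- function(expr) {
  msgs <- character()
  value <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      msgs <<- c(msgs, paste("error:", conditionMessage(e)))
      NULL
    }),
    warning = function(w) {
      msgs <<- c(msgs, trimws(conditionMessage(w)))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  list(value = value, messages = msgs)
}

check_fit_preconditions <- function(data, spec) {
  r <- roles(data)
  if (is.null(r$response)) {
    stop("data has no response column; fit needs one", call. = FALSE)
  }
  if (nrow(data) < length(spec$terms) + 1L) {
    stop("need at least ", length(spec$terms) + 1L, " rows to fit ",
         length(spec$terms), " fixed terms", call. = FALSE)
  }
  invisible(r)
}

finalize_mermod <- function(obj, spec, n, keep_fit) {
  fit <- obj$value
  msgs <- obj$messages
  if (is.null(fit)) return(new_fit_result(spec, "failed", msgs, nobs = n))

  beta <- lme4::fixef(fit)
  # align lme4's term names (a:b products keep their backticks stripped)
  names(beta) <- gsub("`", "", names(beta), fixed = TRUE)
  beta <- beta[spec$terms]
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  names(se) <- names(beta)
  wald <- ifelse(se > 0, beta / se, NA_real_)

  vc <- as.data.frame(lme4::VarCorr(fit))
  grp_rows <- vc$grp != "Residual"
  variances <- stats::setNames(vc$vcov[grp_rows], vc$grp[grp_rows])
  variances <- variances[spec$grouping]
  names(variances) <- spec$grouping
  resid <- if (spec$family == "gaussian") stats::sigma(fit)^2 else NULL

  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) msgs <- c(msgs, "boundary (singular) fit: a variance component is estimated at 0")
  status <- if (length(msgs) || singular) "converged_with_warning" else "converged"

  model <- mixed_model(spec, beta, variances, resid)
  # REML criterion for LMMs; Laplace log-likelihood for GLMMs
  objective <- if (spec$family == "gaussian") as.numeric(lme4::REMLcrit(fit))
               else as.numeric(stats::logLik(fit))
  new_fit_result(spec, status, msgs, model = model, std_errors = se,
                 wald = wald, objective = objective, nobs = n,
                 fit = if (keep_fit) fit else NULL)
}

# grouping-free fallback: ordinary (generalized) linear model
finalize_fixed_only <- function(data, spec, family, keep_fit) {
  r <- roles(data)
  fo <- stats::as.formula(
    paste0("`", r$response, "` ~ ",
           if (length(spec$fixed_effects))
             paste(paste0("`", gsub(":", "`:`", spec$fixed_effects,
                                    fixed = TRUE), "`"), collapse = " + ")
           else "1"),
    env = globalenv())
  n <- nrow(data)
  if (family == "binomial") {
    obj <- collect_conditions(
      stats::glm(fo, data = data, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
    fit <- obj$value
    if (is.null(fit) || !fit$converged) {
      return(new_fit_result(spec, "failed",
                            c(obj$messages, "IRLS did not converge"),
                            nobs = n))
    }
    objective <- as.numeric(stats::logLik(fit))
    resid <- NULL
  } else {
    obj <- collect_conditions(stats::lm(fo, data = data))
    fit <- obj$value
    if (is.null(fit)) return(new_fit_result(spec, "failed", obj$messages,
                                            nobs = n))
    objective <- as.numeric(stats::logLik(fit))
    resid <- summary(fit)$sigma^2
  }
  beta <- stats::coef(fit)
  names(beta) <- gsub("`", "", names(beta), fixed = TRUE)
  beta <- beta[spec$terms]
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(beta)
  wald <- ifelse(se > 0, beta / se, NA_real_)
  model <- mixed_model(spec, beta, numeric(), resid)
  status <- if (length(obj$messages)) "converged_with_warning" else "converged"
  new_fit_result(spec, status, obj$messages, model = model,
                 std_errors = se, wald = wald, objective = objective,
                 nobs = n, fit = if (keep_fit) fit else NULL)
}

#' Fit a linear mixed model by REML
#'
#' Estimates a Gaussian mixed model with crossed random intercepts by
#' restricted maximum likelihood (via \code{\link[lme4]{lmer}}), returning
#' coefficient estimates, variance components, standard errors and Wald
#' t values. Estimation is deterministic: refitting the same table twice
#' gives identical results. Non-convergence never raises an error here;
#' it is reported through the \code{status} field so that a power scan
#' can carry on.
#'
#' Variance estimates are bounded below by zero; boundary (singular) fits
#' are flagged \code{converged_with_warning}, not rejected. A spec with
#' no grouping factors falls back to ordinary least squares.
#'
#' @param data an \code{obs_table} with a numeric response.
#' @param spec a Gaussian \code{model_spec}.
#' @param control an \code{\link[lme4]{lmerControl}} object.
#' @param keep_fit keep the underlying fitted object in the result?
#' @return a \code{cp_fit}: list with \code{model} (estimated
#'   \code{mixed_model}), \code{std_errors}, \code{wald},
#'   \code{objective} (REML criterion), \code{status} (one of
#'   \code{converged}, \code{converged_with_warning}, \code{failed}) and
#'   \code{messages}.
#' @export
fit_lmm <- function(data, spec,
                    control = lme4::lmerControl(calc.derivs = FALSE),
                    keep_fit = TRUE) {
  if (spec$family != "gaussian") {
    stop("fit_lmm needs a gaussian spec; use fit_glmm for binomial",
         call. = FALSE)
  }
  r <- check_fit_preconditions(data, spec)
  if (!length(spec$grouping)) {
    return(finalize_fixed_only(data, spec, "gaussian", keep_fit))
  }
  fo <- spec_formula(spec, r$response)
  obj <- collect_conditions(
    lme4::lmer(fo, data = data, REML = TRUE, control = control))
  finalize_mermod(obj, spec, nrow(data), keep_fit)
}

#' Fit a binomial-logit mixed model (Laplace ML)
#'
#' Estimates a binomial GLMM with crossed random intercepts by maximum
#' likelihood under the Laplace approximation (via
#' \code{\link[lme4]{glmer}}; conditional modes found by penalized
#' iteratively reweighted least squares), returning coefficients on the
#' logit scale with Wald z values. A constant (all-0 or all-1) response,
#' complete separation, or non-convergence yields \code{status =
#' "failed"} with a diagnostic rather than an exception. A spec with no
#' grouping factors falls back to ordinary logistic regression.
#'
#' @param data an \code{obs_table} whose response takes values in
#'   \{0, 1\}.
#' @param spec a binomial \code{model_spec}.
#' @param control a \code{\link[lme4]{glmerControl}} object. The default
#'   skips the post-hoc derivative check and uses the nloptr BOBYQA
#'   optimizer, which is substantially faster on refit loops and agrees
#'   closely with lme4's default optimizer.
#' @param keep_fit keep the underlying fitted object in the result?
#' @return a \code{cp_fit}; see \code{\link{fit_lmm}}.
#' @export
fit_glmm <- function(data, spec,
                     control = lme4::glmerControl(calc.derivs = FALSE,
                                                  optimizer = "nloptwrap"),
                     keep_fit = TRUE) {
  if (spec$family != "binomial") {
    stop("fit_glmm needs a binomial spec; use fit_lmm for gaussian",
         call. = FALSE)
  }
  r <- check_fit_preconditions(data, spec)
  y <- data[[r$response]]
  if (!all(y %in% c(0, 1))) {
    stop("binomial response must take values in {0, 1}", call. = FALSE)
  }
  n <- nrow(data)
  if (length(unique(y)) < 2L) {
    return(new_fit_result(spec, "failed",
                          "response is constant (all 0 or all 1)",
                          nobs = n))
  }
  if (!length(spec$grouping)) {
    return(finalize_fixed_only(data, spec, "binomial", keep_fit))
  }
  fo <- spec_formula(spec, r$response)
  obj <- collect_conditions(
    lme4::glmer(fo, data = data, family = stats::binomial(),
                control = control))
  finalize_mermod(obj, spec, n, keep_fit)
}

#' Fit a mixed model, dispatching on the spec's family
#'
#' @inheritParams fit_lmm
#' @param ... passed on to \code{\link{fit_lmm}} or \code{\link{fit_glmm}}.
#' @return a \code{cp_fit}.
#' @export
fit_mixed <- function(data, spec, ...) {
  if (spec$family == "binomial") fit_glmm(data, spec, ...)
  else fit_lmm(data, spec, ...)
}

#' Evaluate which effects are significant in a fit
#'
#' Applies the rule that effect \eqn{i} is significant iff
#' \eqn{|wald_i| >} its critical value (strict inequality). Failed fits
#' return an all-\code{NA} vector carrying an \code{unusable} attribute:
#' such fits never enter a power numerator or denominator.
#'
#' @param fit a \code{cp_fit}.
#' @param rule a \code{\link{significance_rule}} (or a bare numeric
#'   threshold).
#' @param effects which terms to evaluate; defaults to all non-intercept
#'   terms.
#' @return named logical vector over \code{effects}.
#' @export
evaluate_significance <- function(fit, rule, effects = NULL) {
  spec <- if (!is.null(fit$model)) fit$model$spec else attr(fit, "spec")
  all_terms <- names(fit$wald)
  if (is.null(effects)) effects <- setdiff(all_terms, "(Intercept)")
  absent <- setdiff(effects, all_terms)
  if (length(absent)) {
    stop("unknown effect(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  crit <- resolve_rule(rule, effects)
  if (fit$status == "failed") {
    out <- stats::setNames(rep(NA, length(effects)), effects)
    attr(out, "unusable") <- TRUE
    return(out)
  }
  abs(fit$wald[effects]) > crit
}

#' @export
print.cp_fit <- function(x, ...) {
  cat("Mixed-model fit [", x$status, "]\n", sep = "")
  if (length(x$messages)) {
    cat(paste0("  note: ", x$messages, collapse = "\n"), "\n")
  }
  if (is.null(x$model)) return(invisible(x))
  spec <- x$model$spec
  if (length(x$model$variances) || !is.null(x$model$residual_variance)) {
    cat("Random effects:\n")
    vtab <- data.frame(Groups = c(names(x$model$variances),
                                  if (!is.null(x$model$residual_variance))
                                    "Residual"),
                       Name = c(rep("(Intercept)",
                                    length(x$model$variances)),
                                if (!is.null(x$model$residual_variance)) ""),
                       Variance = c(unname(x$model$variances),
                                    x$model$residual_variance))
    vtab$Std.Dev. <- sqrt(vtab$Variance)
    print(vtab, row.names = FALSE, digits = 5)
  }
  cat("Number of obs:", x$nobs, "\n")
  cat("Fixed effects:\n")
  stat_lab <- if (spec$family == "binomial") "z value" else "t value"
  ftab <- data.frame(Estimate = unname(x$model$beta),
                     `Std. Error` = unname(x$std_errors),
                     stat = unname(x$wald),
                     check.names = FALSE,
                     row.names = names(x$model$beta))
  names(ftab)[3] <- stat_lab
  print(ftab, digits = 5)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes estimates, standard errors, Wald statistics, variance
#' components, objective, status and messages as a JSON object.
#'
#' @param fit a \code{cp_fit}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    status = fit$status,
    family = if (!is.null(fit$model)) fit$model$spec$family else NULL,
    estimates = if (!is.null(fit$model)) as.list(fit$model$beta),
    std_errors = as.list(fit$std_errors),
    wald = as.list(fit$wald),
    variances = if (!is.null(fit$model)) as.list(fit$model$variances),
    residual_variance = if (!is.null(fit$model))
      fit$model$residual_variance,
    objective = fit$objective,
    nobs = fit$nobs,
    messages = fit$messages)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
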