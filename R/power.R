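#' Plan a power scan
#'
#' A scan plan says which grouping factor to vary (\code{simvar}), over
#' which target level counts (\code{steps}), how many simulate--refit
#' repetitions to run per step (\code{nsim}; at least 1000 is
#' recommended for a final simulation) and from which base seed. Power
#' can be estimated in two modes: \emph{databased} uses the model's own
#' coefficients; \emph{sesoi} replaces them with a smallest effect size
#' of interest vector before simulating (a common convention is all
#' coefficients shrunk by 15\%). Both modes share per-repetition seeds,
#' so their comparison is paired.
#'
#' For two-random-variable scans (\code{\link{run_r2_scan}}), a second
#' factor \code{r2var} is held at a fixed level count \code{r2level}
#' while \code{simvar} is scanned.
#'
#' @param simvar grouping-factor name to vary.
#' @param steps integer vector of target level counts (all >= 2).
#' @param nsim repetitions per step (default 1000).
#' @param seed base seed; every repetition derives its own seed from it.
#' @param databased run the databased mode?
#' @param sesoi optional full-length coefficient vector (including
#'   intercept) enabling the sesoi mode.
#' @param r2var,r2level optional second grouping factor and its fixed
#'   level count (jointly present or absent).
#' @return a \code{scan_plan}.
#' @export
scan_plan <- function(simvar, steps, nsim = 1000, seed = 1L,
                      databased = TRUE, sesoi = NULL,
                      r2var = NULL, r2level = NULL) {
  steps <- as.integer(steps)
  if (!length(steps) || anyNA(steps) || any(steps < 2L)) {
    stop("`steps` must be a non-empty vector of integers >= 2",
         call. = FALSE)
  }
  nsim <- as.integer(nsim)
  if (is.na(nsim) || nsim < 1L) stop("`nsim` must be >= 1", call. = FALSE)
  if (is.null(r2var) != is.null(r2level)) {
    stop("`r2var` and `r2level` must be given together", call. = FALSE)
  }
  if (!is.null(r2level)) {
    r2level <- as.integer(r2level)
    if (is.na(r2level) || r2level < 2L) stop("`r2level` must be >= 2",
                                             call. = FALSE)
  }
  if (!isTRUE(databased) && is.null(sesoi)) {
    stop("nothing to run: enable `databased` and/or supply `sesoi`",
         call. = FALSE)
  }
  structure(list(simvar = as.character(simvar)[1L], steps = steps,
                 nsim = nsim, seed = as.integer(seed),
                 databased = isTRUE(databased),
                 sesoi = if (!is.null(sesoi)) as.numeric(sesoi),
                 r2var = r2var, r2level = r2level),
            class = "scan_plan")
}

#' Exact binomial (Clopper--Pearson) confidence interval, in percent
#'
#' Inverts the binomial tail probabilities through beta quantiles:
#' the lower bound is the \eqn{(1-level)/2} quantile of
#' \eqn{Beta(k, n-k+1)} (0 when \eqn{k = 0}) and the upper bound the
#' \eqn{1-(1-level)/2} quantile of \eqn{Beta(k+1, n-k)} (100\% when
#' \eqn{k = n}).
#'
#' @param k number of significant repetitions (successes).
#' @param n number of valid repetitions (trials), >= 1.
#' @param level confidence level in (0, 1); default 0.95.
#' @return named numeric vector \code{c(low, high)} in percent.
#' @examples
#' clopper_pearson(167, 1000)  # c(14.44, 19.16) to two decimals
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  k <- as.numeric(k); n <- as.numeric(n)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer counts with 0 <= k <= n and n >= 1", call. = FALSE)
  }
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = 100 * low, high = 100 * high)
}

# shared simulate--refit--count engine behind run_power_scan / run_r2_scan /
# estimate_type1
power_scan_engine <- function(model, data, effects, plan, rule,
                              level = 0.95, progress = FALSE,
                              extra_meta = list()) {
  if (!inherits(model, "mixed_model")) stop("`model` must be a mixed_model",
                                            call. = FALSE)
  if (!inherits(plan, "scan_plan")) stop("`plan` must be a scan_plan",
                                         call. = FALSE)
  spec <- model$spec
  r <- roles(data)
  if (!plan$simvar %in% r$grouping) {
    stop("simvar '", plan$simvar, "' is not a grouping factor of the data",
         call. = FALSE)
  }
  if (!is.null(plan$r2var)) {
    if (!plan$r2var %in% r$grouping) {
      stop("r2var '", plan$r2var, "' is not a grouping factor of the data",
           call. = FALSE)
    }
    if (identical(plan$r2var, plan$simvar)) {
      stop("r2var must differ from simvar", call. = FALSE)
    }
  }
  if (is.null(effects)) effects <- spec$fixed_effects
  absent <- setdiff(effects, spec$terms)
  if (length(absent)) {
    stop("unknown effect(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rule)) rule <- default_rule(spec$family)
  crit <- resolve_rule(rule, effects)
  if (!is.null(plan$sesoi) && length(plan$sesoi) != length(model$beta)) {
    stop("SESOI vector must have length ", length(model$beta),
         " (including the intercept)", call. = FALSE)
  }

  models <- list()
  if (plan$databased) models$databased <- model
  if (!is.null(plan$sesoi)) {
    models$sesoi <- override_coefficients(model, plan$sesoi)
  }
  modes <- names(models)
  refit <- if (spec$family == "binomial") fit_glmm else fit_lmm

  n_eff <- length(effects); n_step <- length(plan$steps)
  n_mode <- length(modes)
  k_sig <- array(0L, c(n_eff, n_step, n_mode),
                 dimnames = list(effects, plan$steps, modes))
  n_valid <- matrix(0L, n_step, n_mode,
                    dimnames = list(plan$steps, modes))
  n_failed <- matrix(0L, n_step, n_mode,
                     dimnames = list(plan$steps, modes))
  log_rows <- vector("list", n_step * plan$nsim * n_mode)
  li <- 0L

  for (si in seq_len(n_step)) {
    step <- plan$steps[si]
    for (rep_i in seq_len(plan$nsim)) {
      rs <- derive_seed(plan$seed, si, rep_i)
      nd <- resize_by_factor(data, plan$simvar, step,
                             seed = derive_seed(rs, 1L))
      if (!is.null(plan$r2var)) {
        nd <- resize_by_factor(nd, plan$r2var, plan$r2level,
                               seed = derive_seed(rs, 2L))
      }
      sim_seed <- derive_seed(rs, 3L)
      for (mode in modes) {
        y <- simulate_response(models[[mode]], nd, seed = sim_seed)
        fit <- refit(set_response(nd, y), spec, keep_fit = FALSE)
        li <- li + 1L
        if (fit$status == "failed") {
          n_failed[si, mode] <- n_failed[si, mode] + 1L
          log_rows[[li]] <- data.frame(step = step, rep = rep_i,
                                       mode = mode, effect = effects,
                                       wald = NA_real_,
                                       significant = NA,
                                       status = fit$status)
        } else {
          n_valid[si, mode] <- n_valid[si, mode] + 1L
          w <- fit$wald[effects]
          sig <- abs(w) > crit
          k_sig[, si, mode] <- k_sig[, si, mode] + sig
          log_rows[[li]] <- data.frame(step = step, rep = rep_i,
                                       mode = mode, effect = effects,
                                       wald = unname(w),
                                       significant = unname(sig),
                                       status = fit$status)
        }
      }
    }
    if (progress) {
      message(sprintf("step %d/%d (%s = %d): %d repetitions done",
                      si, n_step, plan$simvar, step, plan$nsim))
    }
  }

  cells <- do.call(rbind, lapply(modes, function(mode) {
    do.call(rbind, lapply(seq_len(n_step), function(si) {
      nv <- n_valid[si, mode]
      do.call(rbind, lapply(effects, function(e) {
        k <- k_sig[e, si, mode]
        if (nv > 0) {
          ci <- clopper_pearson(k, nv, level)
          pow <- 100 * k / nv
        } else {
          ci <- c(low = NA_real_, high = NA_real_)
          pow <- NA_real_
        }
        data.frame(effect = e, step = plan$steps[si], mode = mode,
                   k_significant = as.integer(k), n_valid = as.integer(nv),
                   n_failed = as.integer(n_failed[si, mode]),
                   power_percent = pow, ci_low = unname(ci["low"]),
                   ci_high = unname(ci["high"]))
      }))
    }))
  }))
  rownames(cells) <- NULL
  if (any(n_failed > 0.05 * plan$nsim)) {
    warning("more than 5% of repetitions failed to converge at some ",
            "step; power denominators use valid refits only",
            call. = FALSE)
  }
  if (any(n_valid == 0)) {
    warning("all refits failed at some step; affected cells are NA",
            call. = FALSE)
  }

  meta <- c(list(family = spec$family,
                 terms = spec$terms,
                 beta = as.list(model$beta),
                 variances = as.list(model$variances),
                 residual_variance = model$residual_variance,
                 effects = effects,
                 critical = as.list(crit),
                 ci_level = level,
                 simvar = plan$simvar, steps = plan$steps,
                 nsim = plan$nsim, seed = plan$seed,
                 modes = modes,
                 sesoi = plan$sesoi,
                 r2var = plan$r2var, r2level = plan$r2level,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra_meta)
  structure(list(cells = cells, log = do.call(rbind, log_rows[seq_len(li)]),
                 metadata = meta),
            class = "power_table")
}

#' Run a simulate--refit--count power scan over one grouping factor
#'
#' The three-step Monte Carlo power loop: for each target level count in
#' \code{plan$steps} and each of \code{plan$nsim} repetitions, (1) the
#' design is resized along \code{plan$simvar} and a new response vector
#' is simulated from the model, (2) the model is refit to the simulated
#' data and each effect's Wald statistic is compared against its
#' critical value, and (3) power is the percentage of significant refits
#' among valid ones, reported with an exact binomial confidence
#' interval. Failed refits enter neither numerator nor denominator and
#' are tallied per cell.
#'
#' The whole scan is reproducible from \code{plan$seed}: every
#' repetition's resize and simulation seeds are derived
#' deterministically from (base seed, step index, repetition index).
#'
#' @param model a \code{\link{mixed_model}} (typically from a fit on
#'   pilot data, or built from scratch).
#' @param data an \code{obs_table} matching the model's spec.
#' @param effects term names to report power for; defaults to all
#'   non-intercept fixed effects (the intercept is not an effect of
#'   interest).
#' @param plan a \code{\link{scan_plan}}.
#' @param rule a \code{\link{significance_rule}}; defaults to 2 for
#'   Gaussian t values and 1.96 for binomial z values.
#' @param level confidence level of the power intervals.
#' @param progress emit a message after each step?
#' @return a \code{power_table}: list with \code{cells} (one row per
#'   effect x step x mode), \code{log} (per-repetition audit log) and
#'   \code{metadata}.
#' @export
run_power_scan <- function(model, data, effects = NULL, plan, rule = NULL,
                           level = 0.95, progress = FALSE) {
  if (!is.null(plan$r2var)) {
    stop("plan has a second factor set; use run_r2_scan", call. = FALSE)
  }
  power_scan_engine(model, data, effects, plan, rule, level, progress)
}

#' Two-random-variable power scan
#'
#' A two-step resizing procedure: per repetition the design is first
#' resized along \code{plan$simvar} to the current step value, then
#' along \code{plan$r2var} to the fixed \code{plan$r2level}, before the
#' usual simulate--refit--count. Use it to scan, say, the number of
#' items while holding the participant count at a planned ceiling.
#'
#' @inheritParams run_power_scan
#' @param plan a \code{\link{scan_plan}} with \code{r2var} and
#'   \code{r2level} set.
#' @return a \code{power_table}.
#' @export
run_r2_scan <- function(model, data, effects = NULL, plan, rule = NULL,
                        level = 0.95, progress = FALSE) {
  if (is.null(plan$r2var)) {
    stop("plan lacks r2var/r2level; use run_power_scan", call. = FALSE)
  }
  power_scan_engine(model, data, effects, plan, rule, level, progress)
}

#' Simulate the type-I error rate by zeroing all effects
#'
#' Runs the power scan with every non-intercept coefficient set to zero,
#' so the rejection rate estimates the type-I error of the chosen
#' critical values under the model's random-effect structure. The
#' zeroing is recorded in the table's metadata.
#'
#' @inheritParams run_power_scan
#' @return a \code{power_table} whose \code{metadata$null_model} is
#'   \code{TRUE}.
#' @export
estimate_type1 <- function(model, data, effects = NULL, plan, rule = NULL,
                           level = 0.95, progress = FALSE) {
  beta0 <- model$beta
  beta0[-1L] <- 0
  null_model <- override_coefficients(model, beta0)
  plan$sesoi <- NULL
  plan$databased <- TRUE
  power_scan_engine(null_model, data, effects, plan, rule, level, progress,
                    extra_meta = list(null_model = TRUE,
                                      zeroed_terms = model$spec$fixed_effects))
}

#' Long-format summary of a power table
#'
#' @param table a \code{power_table}.
#' @return a data frame with one row per effect x step x mode
#'   (\code{effect}, \code{step}, \code{mode}, \code{k_significant},
#'   \code{n_valid}, \code{n_failed}, \code{power_percent},
#'   \code{ci_low}, \code{ci_high}), sorted by effect then step then
#'   mode.
#' @export
summarize_table <- function(table) {
  if (!inherits(table, "power_table")) stop("`table` must be a power_table",
                                            call. = FALSE)
  if (!nrow(table$cells)) stop("empty power table", call. = FALSE)
  out <- table$cells[order(table$cells$effect, table$cells$step,
                           table$cells$mode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.power_table <- function(x, ...) {
  md <- x$metadata
  cat("Power scan (", md$family, "): simvar = ", md$simvar,
      ", nsim = ", md$nsim, ", seed = ", md$seed, "\n", sep = "")
  if (!is.null(md$r2var)) {
    cat("  second factor ", md$r2var, " held at ", md$r2level,
        " levels\n", sep = "")
  }
  if (isTRUE(md$null_model)) {
    cat("  null model: all non-intercept coefficients zeroed ",
        "(type-I error simulation)\n", sep = "")
  }
  df <- summarize_table(x)
  df$power_percent <- round(df$power_percent, 2)
  df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a power table to CSV and JSON
#'
#' Writes the long-format cells as CSV, cells + metadata as JSON and,
#' when present, the per-repetition audit log (step, rep, mode, effect,
#' wald, significant, status) as a second CSV so that every power value
#' can be recounted independently.
#'
#' @param table a \code{power_table}.
#' @param csv_path path for the cells CSV.
#' @param json_path path for the JSON (default: CSV path with
#'   \code{.json}).
#' @param audit_path optional path for the audit-log CSV.
#' @return \code{csv_path}, invisibly.
#' @export
write_power_table <- function(table, csv_path,
                              json_path = sub("\\.csv$", ".json", csv_path),
                              audit_path = NULL) {
  utils::write.csv(summarize_table(table), csv_path, row.names = FALSE)
  jsonlite::write_json(list(metadata = table$metadata,
                            cells = summarize_table(table)),
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(audit_path) && !is.null(table$log)) {
    utils::write.csv(table$log, audit_path, row.names = FALSE)
  }
  invisible(csv_path)
}
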