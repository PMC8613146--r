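#' Build a fully crossed design skeleton
#'
#' Creates one row per cell of the full cross of the given grouping
#' factors (the first factor varies fastest, as in
#' \code{\link[base]{expand.grid}}), so every pair of levels appears
#' exactly once and the row count is the product of the level counts.
#' Level IDs are the integers \code{1..count} stored as character.
#'
#' @param factors named integer vector of level counts, e.g.
#'   \code{c(Word = 100, Subject = 20)}; all counts >= 2.
#' @param max_rows guard against accidentally huge crossings.
#' @return a design-only \code{obs_table} whose grouping factors are
#'   \code{names(factors)}.
#' @examples
#' d <- make_crossed_design(c(Word = 100, Subject = 20))
#' nrow(d)  # 2000
#' @export
make_crossed_design <- function(factors, max_rows = 5e6) {
  counts <- as.integer(factors)
  if (is.null(names(factors)) || !all(nzchar(names(factors)))) {
    stop("`factors` must be a named vector of level counts", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 2L)) {
    stop("all level counts must be integers >= 2", call. = FALSE)
  }
  if (prod(as.numeric(counts)) > max_rows) {
    stop("crossed design would have ", format(prod(as.numeric(counts))),
         " rows (> max_rows = ", format(max_rows), ")", call. = FALSE)
  }
  grid <- expand.grid(lapply(stats::setNames(counts, names(factors)),
                             seq_len),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (nm in names(grid)) grid[[nm]] <- as.character(grid[[nm]])
  observation_table(grid, grouping = names(factors))
}

# largest-remainder apportionment of L blocks over the ratio
largest_remainder <- function(ratio, L) {
  quota <- ratio * L
  base <- floor(quota)
  need <- L - sum(base)
  if (need > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(need)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Add a block-constant categorical predictor
#'
#' Assigns one code per level of a blocking factor (e.g. one group code
#' per subject), so the column is constant within each block. The number
#' of blocks per code follows the allocation ratio by largest-remainder
#' rounding; a balanced two-code ratio over an even number of blocks
#' splits them exactly in half. By default codes are assigned to blocks
#' in level first-appearance order (deterministic); a seed shuffles the
#' assignment instead.
#'
#' @param design an \code{obs_table}.
#' @param name new column name.
#' @param codes numeric level codes, e.g. \code{c(-0.5, 0.5)} for sum
#'   coding.
#' @param ratio allocation proportions over \code{codes}, summing to 1;
#'   default balanced.
#' @param blocking_factor grouping factor whose levels receive the codes.
#' @param seed optional seed; if given, blocks are assigned to codes in
#'   shuffled order.
#' @return the design with the new column declared as a covariate.
#' @export
assign_categorical <- function(design, name, codes,
                               ratio = NULL, blocking_factor,
                               seed = NULL) {
  r <- roles(design)
  if (!blocking_factor %in% r$grouping) {
    stop("blocking factor '", blocking_factor,
         "' is not a grouping factor of the design", call. = FALSE)
  }
  codes <- as.numeric(codes)
  if (is.null(ratio)) ratio <- rep(1 / length(codes), length(codes))
  ratio <- as.numeric(ratio)
  if (length(ratio) != length(codes)) {
    stop("`ratio` must have one proportion per code (",
         length(codes), "), got ", length(ratio), call. = FALSE)
  }
  if (abs(sum(ratio) - 1) > 1e-8 || any(ratio < 0)) {
    stop("`ratio` proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  ids <- as.character(design[[blocking_factor]])
  lev <- unique(ids)
  counts <- largest_remainder(ratio, length(lev))
  per_level <- rep(codes, counts)
  if (!is.null(seed)) {
    set.seed(seed)
    per_level <- sample(per_level)
  }
  df <- as.data.frame(design)
  df[[name]] <- per_level[match(ids, lev)]
  observation_table(df, response = r$response,
                    covariates = c(r$covariates, name),
                    grouping = r$grouping)
}

#' Add a level-attached continuous predictor
#'
#' Draws one value from Normal(mean, sd) per level of an attachment
#' factor (e.g. one frequency rating per word) and replicates it across
#' that level's rows. With \code{center = TRUE} the grand mean over
#' observations is subtracted after replication, making the column mean
#' zero; in unbalanced designs this centers on observations, not on
#' levels.
#'
#' @param design an \code{obs_table}.
#' @param name new column name.
#' @param mean,sd parameters of the sampling distribution (\code{sd > 0}).
#' @param attach_factor grouping factor whose levels receive the draws.
#' @param center subtract the grand mean after replication?
#' @param seed optional integer seed.
#' @return the design with the new column declared as a covariate.
#' @export
sample_continuous <- function(design, name, mean = 0, sd = 1,
                              attach_factor, center = FALSE,
                              seed = NULL) {
  r <- roles(design)
  if (!attach_factor %in% r$grouping) {
    stop("attach factor '", attach_factor,
         "' is not a grouping factor of the design", call. = FALSE)
  }
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  ids <- as.character(design[[attach_factor]])
  lev <- unique(ids)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rnorm(length(lev), mean, sd)
  col <- draws[match(ids, lev)]
  if (center) col <- col - mean(col)
  df <- as.data.frame(design)
  df[[name]] <- col
  observation_table(df, response = r$response,
                    covariates = c(r$covariates, name),
                    grouping = r$grouping)
}

#' Built-in worked example: a lexical-decision accuracy design
#'
#' Constructs the package's reference artificial design, emulating a
#' lexical decision study: \code{n_subjects} subjects fully crossed with
#' \code{n_words} words; a sum-coded NativeLanguage predictor (-0.5 =
#' one group, +0.5 = the other) constant within subject and balanced by
#' default; a per-word Frequency rating drawn from Normal(freq_mean,
#' freq_sd) and replicated across subjects, plus its grand-mean-centered
#' copy CenteredFrequency. The defaults (20 subjects x 100 words,
#' Frequency ~ Normal(5, 1)) mirror frequency ratings and design sizes
#' typical of lexical-decision datasets.
#'
#' @param n_subjects,n_words level counts of the two crossed factors.
#' @param codes,ratio group codes and allocation for NativeLanguage.
#' @param freq_mean,freq_sd Frequency sampling distribution.
#' @param seed integer seed for the Frequency draws (the word sample is
#'   the only random ingredient under the default balanced allocation).
#' @return a design-only \code{obs_table} with columns Word, Subject,
#'   NativeLanguage, Frequency, CenteredFrequency.
#' @seealso \code{\link{make_lexdec_model}}
#' @export
make_lexdec_design <- function(n_subjects = 20, n_words = 100,
                               codes = c(-0.5, 0.5), ratio = c(0.5, 0.5),
                               freq_mean = 5, freq_sd = 1, seed = NULL) {
  d <- make_crossed_design(c(Word = n_words, Subject = n_subjects))
  d <- assign_categorical(d, "NativeLanguage", codes = codes, ratio = ratio,
                          blocking_factor = "Subject")
  d <- sample_continuous(d, "Frequency", mean = freq_mean, sd = freq_sd,
                         attach_factor = "Word", center = FALSE,
                         seed = seed)
  df <- as.data.frame(d)
  df$CenteredFrequency <- df$Frequency - mean(df$Frequency)
  observation_table(df,
                    covariates = c("NativeLanguage", "Frequency",
                                   "CenteredFrequency"),
                    grouping = c("Word", "Subject"))
}

#' Built-in worked example: the lexical-decision accuracy model
#'
#' The binomial-logit generative model that pairs with
#' \code{\link{make_lexdec_design}}: accuracy is predicted by
#' NativeLanguage, CenteredFrequency and their interaction, with random
#' intercepts for Subject and Word. The default coefficients
#' (-4.3, 0.35, -0.4, -0.32) and variances (Subject 1.04, Word 0.65)
#' are plausible values for a lexical-decision accuracy GLMM and are the
#' package's reference conditions for power examples and tests.
#'
#' @param beta coefficients for (Intercept, NativeLanguage,
#'   CenteredFrequency, NativeLanguage:CenteredFrequency) on the logit
#'   scale.
#' @param subject_variance,word_variance random-intercept variances.
#' @return a binomial \code{mixed_model}.
#' @export
make_lexdec_model <- function(beta = c(-4.3, 0.35, -0.4, -0.32),
                              subject_variance = 1.04,
                              word_variance = 0.65) {
  spec <- model_spec(c("NativeLanguage", "CenteredFrequency",
                       "NativeLanguage:CenteredFrequency"),
                     grouping = c("Subject", "Word"),
                     family = "binomial")
  mixed_model(spec, beta,
              c(Subject = subject_variance, Word = word_variance))
}
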