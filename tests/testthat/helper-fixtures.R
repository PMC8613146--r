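# Fixture builders shared across the suite. Everything is generated in
# code at test time; seeds are fixed so expected values are stable.

# crossed subject x item Gaussian fixture: x1 is a sum-coded (+-0.5)
# between-subject predictor, x2 a centered per-item continuous predictor
make_toy_lmm <- function(n_subjects = 20, n_items = 10,
                         beta = c(1, 0.6, 0.15),
                         subj_var = 0.5, item_var = 0.1, resid_var = 1,
                         seed = 100) {
  d <- make_crossed_design(c(item = n_items, subject = n_subjects))
  d <- assign_categorical(d, "x1", codes = c(-0.5, 0.5),
                          blocking_factor = "subject")
  d <- sample_continuous(d, "x2", mean = 0, sd = 1,
                         attach_factor = "item", center = TRUE,
                         seed = seed)
  spec <- model_spec(c("x1", "x2"), grouping = c("subject", "item"),
                     family = "gaussian")
  model <- mixed_model(spec, beta,
                       c(subject = subj_var, item = item_var),
                       residual_variance = resid_var)
  list(data = d, model = model, spec = spec)
}

# balanced one-way random-intercept data (g groups x m replicates)
make_oneway <- function(g = 8, m = 6, mu = 10, between_var = 4,
                        within_var = 2.25, seed = 5) {
  set.seed(seed)
  id <- rep(sprintf("g%d", seq_len(g)), each = m)
  y <- mu + rep(rnorm(g, 0, sqrt(between_var)), each = m) +
    rnorm(g * m, 0, sqrt(within_var))
  observation_table(data.frame(y = y, id = id), response = "y",
                    grouping = "id")
}

# closed-form balanced one-way ANOVA variance estimators (the REML
# oracle for balanced designs)
oneway_anova_estimators <- function(data) {
  y <- data$y
  id <- data$id
  m <- as.integer(table(id))[1]
  g <- length(unique(id))
  group_means <- tapply(y, id, mean)
  msw <- sum(tapply(y, id, function(v) sum((v - mean(v))^2))) /
    (g * (m - 1))
  msb <- m * sum((group_means - mean(y))^2) / (g - 1)
  list(between = max(0, (msb - msw) / m), within = msw)
}

# Gauss-Hermite nodes/weights by Golub-Welsch, for quadrature oracles
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values,
       weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E[plogis(eta + U)] for U ~ N(0, var), elementwise over eta
logistic_normal_mean <- function(eta, var, n_nodes = 30) {
  gh <- gauss_hermite(n_nodes)
  u <- sqrt(2 * var) * gh$nodes
  w <- gh$weights / sqrt(pi)
  vapply(eta, function(e) sum(w * stats::plogis(e + u)), numeric(1))
}
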