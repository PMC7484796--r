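# shared fixture builders and independent oracles

# exact area/perimeter of a regular n-gon with circumradius r
regular_polygon <- function(n, r = 1) {
  list(area = n / 2 * r^2 * sin(2 * pi / n),
       perimeter = 2 * n * r * sin(pi / n))
}

# brute-force PRESS: refit with each run left out, predict it, sum squares
press_loo <- function(x, y) {
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(x[-i, , drop = FALSE], y[-i])
    (y[i] - sum(x[i, ] * fit$coefficients))^2
  }, numeric(1)))
}

# sequential (Type-I) sums of squares by explicit projection: RSS drop when
# each block of columns is added to the design matrix
sequential_ss <- function(blocks, y) {
  rss_prev <- sum((y - mean(y))^2)
  x <- matrix(1, nrow = length(y))
  out <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    x <- cbind(x, blocks[[i]])
    rss <- sum(stats::lm.fit(x, y)$residuals^2)
    out[i] <- rss_prev - rss
    rss_prev <- rss
  }
  names(out) <- names(blocks)
  c(out, residual = rss_prev)
}

# dummy blocks for the 2x2 crossover ANOVA in the order
# sequence, subject(sequence), period, treatment
crossover_blocks <- function(data) {
  subj <- factor(data$subject)
  list(
    sequence = stats::model.matrix(~ factor(data$sequence))[, -1, drop = FALSE],
    subject = stats::model.matrix(~ subj)[, -1, drop = FALSE],
    period = stats::model.matrix(~ factor(data$period))[, -1, drop = FALSE],
    treatment = stats::model.matrix(~ factor(data$treatment,
                                             levels = c("R", "T")))[, -1,
                                                                    drop = FALSE]
  )
}

# one-compartment reference specs used across PK tests (immediate-release
# reference, extended-release test emulated by slower absorption)
ir_spec <- function(...) pk_sim_spec(ka = 1.5, ...)
er_spec <- function(...) pk_sim_spec(ka = 0.45, ...)

nca_long_dataset <- function(nca_tab, params = c("cmax", "tmax", "auc_0_t",
                                                 "auc_0_inf")) {
  do.call(rbind, lapply(params, function(p) {
    data.frame(subject = nca_tab$subject, sequence = nca_tab$sequence,
               period = nca_tab$period, treatment = nca_tab$treatment,
               parameter = p, value = nca_tab[[p]],
               stringsAsFactors = FALSE)
  }))
}
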