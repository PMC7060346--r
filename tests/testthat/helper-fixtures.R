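## Shared fixture builders: everything is constructed in code.

## Counting-task trials from parallel vectors.
make_trials <- function(real, reported, confidence = rep(5, length(real)),
                        duration = rep(30, length(real))) {
  data.frame(trial_index = seq_along(real) - 1L, duration_s = duration,
             nbeats_real = real, nbeats_reported = reported,
             confidence = confidence)
}

## Task trials from compact per-type specs: each of go/nogo/choose is a
## list(pressed = 0/1 vector, rt = numeric vector over pressed trials).
make_session <- function(go_rt = numeric(), go_n = length(go_rt),
                         nogo_rt = numeric(), nogo_n = length(nogo_rt),
                         choose_rt = numeric(), choose_n = length(choose_rt),
                         phase = "systole") {
  block <- function(type, n, rts) {
    pressed <- c(rep(1L, length(rts)), rep(0L, n - length(rts)))
    data.frame(trial_type = type, intended_phase = phase,
               pressed = pressed,
               rt_ms = c(rts, rep(NA_real_, n - length(rts))))
  }
  df <- rbind(block("go", go_n, go_rt), block("nogo", nogo_n, nogo_rt),
              block("choose", choose_n, choose_rt))
  df$trial_index <- seq_len(nrow(df)) - 1L
  df
}

## Independent fixed-grid quadrature oracles for the three Bayes factors.
## Deliberately different evaluation routes from the package functions:
## the t-test oracle marginalizes the noncentral-t density over the Cauchy
## effect-size prior (the package integrates over g); the correlation and
## regression oracles use midpoint Riemann sums on transformed finite
## domains.
oracle_bf_ttest <- function(t, n, scale = sqrt(2) / 2, n_grid = 1e5) {
  ## delta = scale * tan(u), u in (-pi/2, pi/2): Cauchy quantile transform
  u <- seq(-pi / 2, pi / 2, length.out = n_grid + 1)
  u <- (u[-1] + u[-length(u)]) / 2
  delta <- scale * tan(u)
  ## dcauchy(delta) * d delta = du / pi; far-tail ncp values trigger
  ## precision warnings from dt() while contributing zero mass
  num <- mean(suppressWarnings(stats::dt(t, n - 1, ncp = delta * sqrt(n))))
  num / stats::dt(t, n - 1)
}

oracle_bf_pearson <- function(r, n, width = 1, n_grid = 1e5) {
  rho <- seq(-1, 1, length.out = n_grid + 1)
  rho <- (rho[-1] + rho[-length(rho)]) / 2
  h <- 2 / n_grid
  ## exact sampling density of r given rho via the hypergeometric series,
  ## accumulated vectorially over the whole grid at once
  f2_vec <- function(x, kmax = 2000) {
    term <- rep(1, length(x)); s <- rep(1, length(x))
    for (k in 0:kmax) {
      term <- term * (0.5 + k)^2 / ((n - 0.5 + k) * (k + 1)) * x
      s <- s + term
      if (max(abs(term)) < 1e-15 * max(abs(s))) break
    }
    s
  }
  lr <- (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
    f2_vec((rho * r + 1) / 2) / f2_vec(0.5)
  a <- 1 / width
  sum(lr * stats::dbeta((rho + 1) / 2, a, a) / 2) * h
}

oracle_bf_regression <- function(f, n, k, scale = sqrt(2) / 4,
                                 n_grid = 1e5) {
  r2 <- k * f / (k * f + n - k - 1)
  ## u = g / (1 + g) maps (0, Inf) to (0, 1)
  u <- seq(0, 1, length.out = n_grid + 1)
  u <- (u[-1] + u[-length(u)]) / 2
  g <- u / (1 - u)
  b <- n * scale^2 / 2
  dens <- exp(0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g)
  integrand <- (1 + g)^((n - 1 - k) / 2) *
    (1 + g * (1 - r2))^(-(n - 1) / 2) * dens / (1 - u)^2
  sum(integrand) / n_grid
}
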