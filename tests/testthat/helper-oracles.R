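# Independent oracle implementations used to check the package's estimators.
# These are written as plain step-by-step evaluations (explicit loops, uniroot
# instead of Newton) so they share no code path with the implementation.

# Step-by-step moderated two-group fit: per-gene means and pooled variances,
# moment matching of log residual variances against a scaled-F prior
# (trigamma inverted with uniroot), posterior variance shrinkage, moderated t.
oracle_moderated_fit <- function(values, a_cols, b_cols) {
  na <- length(a_cols); nb <- length(b_cols); df <- na + nb - 2
  g <- nrow(values)
  mean_a <- mean_b <- s2 <- numeric(g)
  for (i in seq_len(g)) {
    xa <- values[i, a_cols]; xb <- values[i, b_cols]
    mean_a[i] <- sum(xa) / na
    mean_b[i] <- sum(xb) / nb
    s2[i] <- (sum((xa - mean_a[i])^2) + sum((xb - mean_b[i])^2)) / df
  }
  log2fc <- mean_a - mean_b
  e <- log(s2[s2 > 0]) - digamma(df / 2) + log(df / 2)
  emean <- sum(e) / length(e)
  evar <- sum((e - emean)^2) / (length(e) - 1)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    half_d0 <- stats::uniroot(function(x) trigamma(x) - excess,
                              lower = 1e-8, upper = 1e10,
                              tol = .Machine$double.eps^0.8)$root
    d0 <- 2 * half_d0
    s0_sq <- exp(emean + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s_tilde <- if (is.finite(d0)) (d0 * s0_sq + df * s2) / (d0 + df) else rep(s0_sq, g)
  t_mod <- log2fc / sqrt(s_tilde * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t_mod), df = d0 + df)
  list(d0 = d0, s0_sq = s0_sq, log2fc = log2fc, s2 = s2,
       t_moderated = t_mod, p_value = p)
}

# Hand product-limit estimator: at each distinct event time t, the risk set is
# everyone whose observed time is >= t (events precede censorings at ties).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, n_risk = NA_real_, n_event = NA_real_,
                    survival = NA_real_)
  for (k in seq_along(ts)) {
    n <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n)
    out$n_risk[k] <- n; out$n_event[k] <- d; out$survival[k] <- s
  }
  out
}

# Hand two-group log-rank tabulation from the hypergeometric mean/variance at
# each distinct event time.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp == "a")
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == "a")
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p_value = stats::pchisq(chi, 1, lower.tail = FALSE),
       observed_a = O, expected_a = E, variance = V)
}

# Small signed signature used across tests.
demo_signature <- function(n_up = 4, n_down = 2, species = "human",
                           name = "demo") {
  gene_signature(name,
                 up = sprintf("up%02d", seq_len(n_up)),
                 down = sprintf("dn%02d", seq_len(n_down)),
                 species = species)
}

# Random log2-scale expression matrix with named dimensions.
random_matrix <- function(genes, samples, seed = 1, sd = 1, mean = 0) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(length(genes) * length(samples), mean = mean, sd = sd),
                length(genes), length(samples),
                dimnames = list(genes, samples))
    expression_matrix(v, "log2")
  })
}
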