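# The published operating schedule: 300 uL, 16%/min for 2 min (reflex
# tearing), then 11%/min for the remaining 13 min (basal turnover).
paper_schedule <- function(round_beta = TRUE) {
  clearance_schedule(c(0.16, 0.11), c(2, 13), v0 = 300, round_beta = round_beta)
}

# Definitional one-way ANOVA from raw sums of squares; independent of the
# lm()/anova() route used by the package.
anova_oracle <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(y)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, df1 = k - 1, df2 = N - k,
       p = pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Forward-Euler discretization of dV/dt = -beta V with step h; independent
# discrete-compounding oracle for the continuous exponential.
euler_volume <- function(beta, v0, t, h) v0 * (1 - beta * h)^(t / h)
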