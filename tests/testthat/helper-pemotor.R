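# Shared fixtures for the test suite.

# Best-fit reference parameters used throughout.
ref_params <- function() pe_params()

# Normalization constant of the population inner product at the reference
# density (see pe_population): effective single-trial gain = eta * c0.
pop_c0 <- function(params) 1 / (2 * sqrt(pi) * params$sigma * (100 / 360))

# Per-subject test-phase angle curves from a trial table, subjects in rows.
subject_test_curves <- function(table) {
  te <- table[table$phase == "test" & !table$excluded, ]
  t(vapply(split(te, te$subject_id),
           function(d) d$angle_deg[order(d$trial)],
           numeric(max(te$trial) - min(te$trial) + 1)))
}

# Twelve values with exact mean m and sd s whose largest element is `top`
# (affine adjustment of a fixed base set); used for the 3-SD screening case.
moments_fixture <- function(m, s, top, n = 12) {
  z <- seq_len(n - 1)
  b <- (n * m - top) / (n - 1)
  a2 <- ((n - 1) * s^2 - (top - m)^2 - (n - 1) * (b - m)^2) /
    sum((z - mean(z))^2)
  stopifnot(a2 > 0)
  vals <- c(b + sqrt(a2) * (z - mean(z)), top)
  stopifnot(abs(mean(vals) - m) < 1e-9, abs(sd(vals) - s) < 1e-9)
  vals
}
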