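# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation it checks.

# Receptor-noise-limited distance as the noise-weighted distance from the
# log-contrast vector to the achromatic (equal-shift) line, found by 1-D
# numerical minimization rather than the closed form.
rnl_oracle <- function(qA, qB, e) {
  df <- log(qA / qB)
  obj <- function(c) sum(((df - c) / e)^2)
  sqrt(stats::optimize(obj, c(-50, 50), tol = 1e-14)$objective)
}

# Literal Benjamini-Hochberg step-up: sort, scale by n/rank, enforce
# monotonicity from the largest down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ps)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Direct 2-D discrete Fourier transform by explicit matrix products
# (independent of stats::fft).
dft2_direct <- function(x) {
  n <- nrow(x); m <- ncol(x)
  Wn <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  Wm <- exp(-2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  Wn %*% x %*% t(Wm)
}

# Dominant period of an image from the direct DFT: the period of the
# strongest non-DC frequency component.
oracle_dominant_period <- function(x) {
  F <- dft2_direct(x)
  n <- nrow(x); m <- ncol(x)
  fu <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fv <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)[1:m] / m
  P <- Mod(F)^2
  P[1, 1] <- 0
  k <- arrayInd(which.max(P), dim(P))
  1 / sqrt(fu[k[1]]^2 + fv[k[2]]^2)
}

# Hand one-way ANOVA.
anova_f_oracle <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(x) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# Texture builders ------------------------------------------------------

# Horizontal square wave: stripes of width period/2 along rows.
square_wave_image <- function(n, period, amplitude = 1) {
  v <- amplitude * ((floor((0:(n - 1)) / (period / 2)) %% 2 == 0) - 0.5)
  matrix(rep(v, each = n), n, n)
}

checkerboard_image <- function(n, square) {
  outer(0:(n - 1), 0:(n - 1),
        function(r, c) ((floor(r / square) + floor(c / square)) %% 2))
}

full_mask <- function(n, m = n) roi_mask(matrix(TRUE, n, m))

# Bare energy-spectrum constructor for hand-built spectra in tests.
new_spec <- function(scales, energy, multiplier = 1.414) {
  chromatch:::new_energy_spectrum(scales, energy, multiplier)
}

expect_within_one_step <- function(found, target, multiplier = 1.414) {
  expect_gte(found, target / multiplier - 1e-9)
  expect_lte(found, target * multiplier + 1e-9)
}
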