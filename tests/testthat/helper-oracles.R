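# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementation.

# Smallest Otsu threshold by exhaustive search over all 256 candidates.
oracleOtsu <- function(h) {
  lev <- 0:255
  total <- sum(h)
  best <- -Inf; bestT <- NA
  for (t in 0:254) {
    w0 <- sum(h[lev <= t]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lev[lev <= t] * h[lev <= t]) / w0
    mu1 <- sum(lev[lev > t] * h[lev > t]) / w1
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best + 1e-9) { best <- bc; bestT <- t }
  }
  bestT
}

# IsoData fixpoint check: t is a fixpoint of t <- round((mu_below+mu_above)/2).
oracleIsoDataFix <- function(h, t) {
  lev <- 0:255
  lo <- lev <= t; hi <- !lo
  if (sum(h[lo]) == 0 || sum(h[hi]) == 0) return(FALSE)
  m0 <- sum(lev[lo] * h[lo]) / sum(h[lo])
  m1 <- sum(lev[hi] * h[hi]) / sum(h[hi])
  round((m0 + m1) / 2) == t
}

# Huang fuzzy-entropy value for a given threshold (for argmin comparison).
oracleHuangEntropy <- function(h, t) {
  lev <- 0:255
  occ <- which(h > 0)
  C <- (occ[length(occ)] - occ[1])
  lo <- lev <= t
  mu0 <- sum(lev[lo] * h[lo]) / sum(h[lo])
  mu1 <- sum(lev[!lo] * h[!lo]) / sum(h[!lo])
  S <- 0
  for (v in 0:255) {
    if (h[v + 1] == 0) next
    mu <- if (v <= t) 1 / (1 + abs(v - mu0) / C) else 1 / (1 + abs(v - mu1) / C)
    mu <- min(max(mu, 1e-12), 1 - 1e-12)
    S <- S + h[v + 1] * (-mu * log(mu) - (1 - mu) * log(1 - mu))
  }
  S
}

# Direct per-pixel local threshold on a small image: loops over every pixel
# and its disc neighbourhood with replicate padding.
oracleLocalBinary <- function(px, radius, method,
                              prm = octarep::thresholdParams()) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- pmin(pmax(r + offs$dy, 1), nr)
    cc <- pmin(pmax(c + offs$dx, 1), nc)
    vals <- px[cbind(rr, cc)]
    p <- px[r, c]
    out[r, c] <- switch(method,
      local_mean = p > mean(vals) - prm$mean_c,
      local_median = p > sort(vals)[(length(vals) + 1) %/% 2] - prm$median_c,
      local_niblack = {
        sdp <- sqrt(mean(vals^2) - mean(vals)^2)
        p > mean(vals) + prm$niblack_k * sdp - prm$niblack_c
      },
      local_phansalkar = {
        m <- mean(vals) / 255
        s <- sqrt(mean(vals^2) - mean(vals)^2) / 255
        t <- m * (1 + prm$phansalkar_p * exp(-prm$phansalkar_q * m) +
                    prm$phansalkar_k * (s / prm$phansalkar_r - 1))
        p / 255 > t
      },
      local_bernsen = {
        mid <- (max(vals) + min(vals)) / 2
        if ((max(vals) - min(vals)) < prm$bernsen_contrast) mid >= 128
        else p > mid
      },
      local_otsu = p > oracleOtsu(tabulate(vals + 1L, nbins = 256L)))
  }
  out
}

# One-way and two-way ANOVA mean squares through lm/anova (independent of
# the package's direct sums-of-squares).
oracleOnewayICC <- function(grid) {
  d <- data.frame(y = as.vector(grid),
                  subj = factor(rep(seq_len(nrow(grid)), ncol(grid))))
  a <- anova(lm(y ~ subj, d))
  msb <- a["subj", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
  k <- ncol(grid)
  (msb - msw) / (msb + (k - 1) * msw)
}

oracleTwowayICC <- function(grid) {
  d <- data.frame(y = as.vector(grid),
                  subj = factor(rep(seq_len(nrow(grid)), ncol(grid))),
                  cond = factor(rep(seq_len(ncol(grid)), each = nrow(grid))))
  a <- anova(lm(y ~ subj + cond, d))
  msr <- a["subj", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
  k <- ncol(grid)
  (msr - mse) / (msr + (k - 1) * mse)
}

randomHistogram <- function() {
  h <- integer(256)
  nmodes <- sample(1:3, 1)
  for (i in seq_len(nmodes)) {
    centre <- sample(0:255, 1)
    vals <- pmin(255, pmax(0, round(rnorm(sample(50:400, 1), centre,
                                          runif(1, 2, 40)))))
    h <- h + tabulate(vals + 1L, nbins = 256L)
  }
  h
}

smallRandomImage <- function(n = 32, pitch = 10) {
  GrayImage(matrix(sample(0:255, n * n, replace = TRUE), n, n), pitch)
}
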