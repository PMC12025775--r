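# Independent oracles, deliberately scalar / closed-form and coded apart from
# the package internals they are used to check.

# Small hand-made lookup table with well-separated colors.
toy_table <- function() {
  reference_table(c(20, 80, 140),
                  rbind(c(0, 0, 0), c(100, 100, 100), c(200, 200, 200)))
}

# Scalar triple-loop nearest-color classification (ties -> smallest thickness).
brute_force_classify <- function(image, table) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      best <- Inf; best_t <- NA_real_
      for (k in seq_along(table$thickness_nm)) {
        d <- 0
        for (ch in 1:3) d <- d + (image[i, j, ch] - table$colors[k, ch])^2
        if (d < best) { best <- d; best_t <- table$thickness_nm[k] }
      }
      out[i, j] <- best_t
    }
  }
  out
}

# Scalar spectral-integration oracle for one thickness: loop over wavelengths,
# accumulate XYZ, convert to 8-bit RGB. No vectorization, no shared code path.
scalar_reference_rgb <- function(T, n_lipid = 1.48, n_water = 1.336,
                                 wl = seq(380, 780, by = 5),
                                 gamma_encode = TRUE) {
  r1 <- (1 - n_lipid) / (1 + n_lipid)
  r2 <- (n_lipid - n_water) / (n_lipid + n_water)
  gain <- (abs(r1) + abs(r2))^2
  lobe <- function(l, mu, s1, s2) {
    s <- if (l < mu) s1 else s2
    exp(-0.5 * ((l - mu) / s)^2)
  }
  X <- 0; Y <- 0; Z <- 0; Xw <- 0; Yw <- 0; Zw <- 0
  for (l in wl) {
    refl <- (r1^2 + r2^2 + 2 * r1 * r2 * cos(4 * pi * n_lipid * T / l)) / gain
    cx <- 1.056 * lobe(l, 599.8, 37.9, 31.0) +
          0.362 * lobe(l, 442.0, 16.0, 26.7) -
          0.065 * lobe(l, 501.1, 20.4, 26.2)
    cy <- 0.821 * lobe(l, 568.8, 46.9, 40.5) +
          0.286 * lobe(l, 530.9, 16.3, 31.1)
    cz <- 1.217 * lobe(l, 437.0, 11.8, 36.0) +
          0.681 * lobe(l, 459.0, 26.0, 13.8)
    X <- X + refl * cx; Y <- Y + refl * cy; Z <- Z + refl * cz
    Xw <- Xw + cx; Yw <- Yw + cy; Zw <- Zw + cz
  }
  M <- matrix(c( 3.2406, -1.5372, -0.4986,
                -0.9689,  1.8758,  0.0415,
                 0.0557, -0.2040,  1.0570), nrow = 3, byrow = TRUE)
  rgb <- as.numeric(M %*% c(X, Y, Z))
  white <- as.numeric(M %*% c(Xw, Yw, Zw))
  out <- numeric(3)
  for (ch in 1:3) {
    u <- min(max(rgb[ch] / white[ch], 0), 1)
    if (gamma_encode)
      u <- if (u <= 0.0031308) 12.92 * u else 1.055 * u^(1 / 2.4) - 0.055
    out[ch] <- round(u * 255)
  }
  out
}

# Closed-form t-test oracles built directly from the textbook formulas.
oracle_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Sup-distance of the empirical CDF of x from N(mean(x), sd(x)), by
# enumerating the CDF steps.
oracle_ks_stat <- function(x) {
  x <- sort(x)
  n <- length(x)
  Fx <- pnorm(x, mean(x), sd(x))
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}
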