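# Independent brute-force oracles. Deliberately written as plain, slow,
# double-loop R so they share no code path with the package kernels.

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(0)
  if (A == 0) return(log(B * (n - m)))
  -log(A / B)
}

oracle_fuzzyen <- function(x, m, r, nf) {
  n <- length(x)
  nt <- n - m
  templ <- function(i, mm) {
    v <- x[i:(i + mm - 1)]
    v - mean(v)
  }
  sm <- 0; sm1 <- 0; np <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(templ(i, m) - templ(j, m)))
      d1 <- max(abs(templ(i, m + 1) - templ(j, m + 1)))
      sm <- sm + exp(-(d / r)^nf)
      sm1 <- sm1 + exp(-(d1 / r)^nf)
      np <- np + 1
    }
  }
  log(sm / np) - log(sm1 / np)
}

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    s <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

# ordinal-pattern histogram via stable argsort keys
oracle_pe <- function(x, d, tau) {
  n <- length(x)
  nt <- n - (d - 1) * tau
  keys <- character(nt)
  for (i in 1:nt) {
    v <- x[i + (0:(d - 1)) * tau]
    keys[i] <- paste(order(v), collapse = ".")
  }
  p <- table(keys) / nt
  -sum(p * log(p))
}

# exhaustive enumeration of all monotone warping paths (lengths <= ~6)
oracle_dtw <- function(a, b) {
  rec <- function(i, j) {
    d <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(d)
    cands <- Inf
    if (i > 1) cands <- min(cands, rec(i - 1, j))
    if (j > 1) cands <- min(cands, rec(i, j - 1))
    if (i > 1 && j > 1) cands <- min(cands, rec(i - 1, j - 1))
    d + cands
  }
  rec(length(a), length(b))
}

# fraction of total FFT power falling in [lo, hi) Hz
oracle_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  pw <- Mod(fft(x))^2
  freq <- (0:(n - 1)) * fs / n
  keep <- freq <= fs / 2
  sum(pw[keep & freq >= lo & freq < hi]) / sum(pw[keep])
}

# deterministic test signals
sin_wave <- function(f, fs = 128, secs = 5, phase = 0) {
  sin(2 * pi * f * (0:(round(fs * secs) - 1)) / fs + phase)
}

small_brem <- function(seed, channel = "O1", n = 640, fs = 128) {
  set.seed(seed)
  build_brem(eeg_signal(rnorm(n), fs, channel = channel))
}
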