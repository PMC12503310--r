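`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic signal via FFT; input must be real
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# trapezoidal integral of y over x (both inclusive of end points)
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# von Mises(0, kappa) sampler, Best & Fisher (1979) rejection scheme
.rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# mean resultant length of von Mises(kappa): I1(kappa)/I0(kappa)
.vmResultant <- function(kappa) {
  if (kappa == 0) return(0)
  if (!is.finite(kappa)) return(1)
  # expon.scaled avoids overflow at large kappa
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

.assert <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# short deterministic polynomial hash over serialized bytes, for traceability
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
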