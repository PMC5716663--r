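# Internal exact rational arithmetic.
#
# Numerators and denominators are stored as integer-valued doubles, which are
# exact below 2^53.  Every operation reduces by gcd and returns NULL on
# (potential) overflow, at which point callers fall back to floating point.

.MAX_EXACT <- 2^53

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

.rat <- function(num, den) {
  if (den == 0) return(NULL)
  if (abs(num) > .MAX_EXACT || abs(den) > .MAX_EXACT) return(NULL)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  if (num == 0) return(c(num = 0, den = 1))
  g <- .gcd(num, den)
  c(num = num / g, den = den / g)
}

.rat_add <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  .rat(a[[1]] * b[[2]] + b[[1]] * a[[2]], a[[2]] * b[[2]])
}

.rat_mul <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  # cross-reduce first to delay overflow
  g1 <- .gcd(a[[1]], b[[2]])
  g2 <- .gcd(b[[1]], a[[2]])
  if (g1 == 0) g1 <- 1
  if (g2 == 0) g2 <- 1
  .rat((a[[1]] / g1) * (b[[1]] / g2), (a[[2]] / g2) * (b[[2]] / g1))
}

.rat_div <- function(a, b) {
  if (is.null(a) || is.null(b) || b[[1]] == 0) return(NULL)
  .rat_mul(a, c(b[[2]], b[[1]]))
}

.rat_pow <- function(a, k) {
  if (is.null(a)) return(NULL)
  out <- c(num = 1, den = 1)
  for (i in seq_len(k)) {
    out <- .rat_mul(out, a)
    if (is.null(out)) return(NULL)
  }
  out
}

.rat_sum <- function(lst) {
  out <- c(num = 0, den = 1)
  for (r in lst) {
    out <- .rat_add(out, r)
    if (is.null(out)) return(NULL)
  }
  out
}

.rat_value <- function(a) a[[1]] / a[[2]]

# Exact rational reconstruction of a double by continued fractions.  Succeeds
# only if num/den reproduces x bit-exactly; returns NULL otherwise, so 1/3
# entered as 1/3 is recovered but arbitrary irrationals are not forced.
.as_rational <- function(x, max_den = 1e6) {
  if (!is.finite(x)) return(NULL)
  neg <- x < 0
  x0 <- abs(x)
  if (x0 == round(x0)) {
    if (x0 > .MAX_EXACT) return(NULL)
    return(c(num = if (neg) -x0 else x0, den = 1))
  }
  p0 <- 0; q0 <- 1
  p1 <- 1; q1 <- 0
  r <- x0
  for (i in 1:64) {
    a <- floor(r)
    p <- a * p1 + p0
    q <- a * q1 + q0
    if (q > max_den || p > .MAX_EXACT) return(NULL)
    if (q > 0 && p / q == x0) {
      return(.rat(if (neg) -p else p, q))
    }
    frac <- r - a
    if (frac == 0) return(NULL)
    r <- 1 / frac
    p0 <- p1; q0 <- q1
    p1 <- p; q1 <- q
  }
  NULL
}

.lcm2 <- function(a, b) {
  g <- .gcd(a, b)
  if (g == 0) return(0)
  (a / g) * b
}
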