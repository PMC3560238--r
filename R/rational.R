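# Exact rational arithmetic on parallel numerator/denominator arrays.
#
# A rational array is a plain list(n = <numeric>, d = <numeric>) whose
# components are doubles holding integers, with d > 0 and gcd(n, d) = 1
# elementwise.  Shapes (vector or matrix) are carried by the arrays
# themselves.  Every operation reduces and guards against leaving the
# range in which double-precision integer arithmetic is exact; at the
# desk scales this package targets the guard never fires.

.RQ_MAX <- 2^52

rq_guard <- function(...) {
  for (x in list(...)) {
    if (any(abs(x) >= .RQ_MAX)) {
      stop("exact rational arithmetic overflow: intermediate value exceeds 2^52",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

# vectorized Euclid on nonnegative integers (recycles to common length)
rq_gcd <- function(a, b) {
  L <- max(length(a), length(b))
  a <- rep_len(abs(a), L)
  b <- rep_len(abs(b), L)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a)
    b <- r
  }
  a
}

rq_lcm <- function(a, b) {
  g <- rq_gcd(a, b)
  out <- a / g * b
  rq_guard(out)
  out
}

# canonical form: d > 0, reduced, 0 represented as 0/1
rq_canon <- function(n, d) {
  if (any(d == 0)) stop("zero denominator in rational", call. = FALSE)
  s <- sign(d)
  n <- n * s
  d <- d * s
  g <- rq_gcd(n, d)
  g[g == 0] <- 1
  n <- n / g
  d <- d / g
  d[n == 0] <- 1
  rq_guard(n, d)
  list(n = n, d = d)
}

rq_int <- function(x) list(n = x, d = x * 0 + 1)

rq_neg <- function(x) list(n = -x$n, d = x$d)

rq_add <- function(x, y) {
  t1 <- x$n * y$d
  t2 <- y$n * x$d
  d <- x$d * y$d
  rq_guard(t1, t2, d)
  n <- t1 + t2
  rq_guard(n)
  rq_canon(n, d)
}

rq_sub <- function(x, y) rq_add(x, rq_neg(y))

rq_mul <- function(x, y) {
  g1 <- rq_gcd(x$n, y$d)
  g1[g1 == 0] <- 1
  g2 <- rq_gcd(y$n, x$d)
  g2[g2 == 0] <- 1
  n <- (x$n / g1) * (y$n / g2)
  d <- (x$d / g2) * (y$d / g1)
  rq_guard(n, d)
  rq_canon(n, d)
}

rq_div <- function(x, y) {
  if (any(y$n == 0)) stop("rational division by zero", call. = FALSE)
  rq_mul(x, list(n = y$d, d = y$n))
}

# sign of x - y, elementwise
rq_cmp <- function(x, y) {
  t1 <- x$n * y$d
  t2 <- y$n * x$d
  rq_guard(t1, t2)
  sign(t1 - t2)
}

rq_to_num <- function(x) x$n / x$d

# exact rational dot product of two rq vectors
rq_dot <- function(x, y) {
  p <- rq_mul(x, y)
  acc <- list(n = 0, d = 1)
  for (i in seq_along(p$n)) {
    acc <- rq_add(acc, list(n = p$n[i], d = p$d[i]))
  }
  acc
}

rq_elt <- function(x, i) list(n = x$n[i], d = x$d[i])

rq_row <- function(M, i) list(n = M$n[i, ], d = M$d[i, ])

# Convert doubles to exact rationals.  Integers pass through; other values
# go through a continued-fraction expansion and must be matched to within
# `tol` with denominator at most `max_den`, otherwise the value is rejected
# as not exactly representable.
rq_from_num <- function(x, max_den = 1e6, tol = 1e-9) {
  shape <- dim(x)
  xv <- as.numeric(x)
  n <- numeric(length(xv))
  d <- numeric(length(xv))
  for (i in seq_along(xv)) {
    v <- xv[i]
    if (!is.finite(v)) stop("non-finite value cannot be converted to a rational", call. = FALSE)
    if (v == round(v)) {
      n[i] <- v
      d[i] <- 1
      next
    }
    # continued-fraction convergents p/q
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    z <- v
    ok <- FALSE
    for (k in 1:64) {
      a <- floor(z)
      p2 <- a * p1 + p0
      q2 <- a * q1 + q0
      if (q2 > max_den) break
      if (abs(v - p2 / q2) <= tol * max(1, abs(v))) {
        n[i] <- p2
        d[i] <- q2
        ok <- TRUE
        break
      }
      frac <- z - a
      if (frac == 0) break
      z <- 1 / frac
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    }
    if (!ok) {
      stop(sprintf("value %.12g is not representable as an exact rational (max denominator %g)",
                   v, max_den), call. = FALSE)
    }
  }
  if (!is.null(shape)) {
    dim(n) <- shape
    dim(d) <- shape
  }
  rq_canon(n, d)
}

# Scale a rational vector to its smallest integer form: multiply by the lcm
# of denominators, divide by the gcd of numerators.  Orientation is kept
# unless positive_first, in which case the first nonzero entry is made > 0.
rq_smallest_int <- function(v, positive_first = FALSE) {
  if (all(v$n == 0)) return(v$n * 0)
  L <- 1
  for (dd in v$d) L <- rq_lcm(L, dd)
  ints <- v$n * (L / v$d)
  rq_guard(ints)
  g <- 0
  for (nn in ints) g <- rq_gcd(g, nn)
  ints <- ints / g
  if (positive_first) {
    fz <- ints[ints != 0][1]
    if (fz < 0) ints <- -ints
  }
  ints
}
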