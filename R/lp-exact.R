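# Exact rational linear programming.
#
# A two-phase primal simplex over exact rationals with Bland's rule
# (guaranteed termination, no degeneracy cycling, no feasibility
# tolerance).  Every loop/certificate decision in this package reduces to
# the feasibility or sign of an optimum of such an LP, and the loop-law
# dichotomy would be corrupted by floating-point tie-breaking, so the
# solver is exact end to end.  Problems here are desk-scale (tens of
# variables); performance beyond that is a non-goal.

# full-tableau pivot on (r, e); last row of the tableau is the cost row
.lp_pivot <- function(Tn, Td, r, e) {
  piv <- list(n = Tn[r, e], d = Td[r, e])
  row <- rq_mul(list(n = Tn[r, ], d = Td[r, ]), list(n = piv$d, d = piv$n))
  Tn[r, ] <- row$n
  Td[r, ] <- row$d
  cn <- Tn[, e]
  cd <- Td[, e]
  cn[r] <- 0
  cd[r] <- 1
  act <- which(cn != 0)
  if (length(act)) {
    K <- ncol(Tn)
    Cm <- list(n = matrix(cn[act], length(act), K), d = matrix(cd[act], length(act), K))
    Rm <- list(n = matrix(row$n, length(act), K, byrow = TRUE),
               d = matrix(row$d, length(act), K, byrow = TRUE))
    P <- rq_mul(Cm, Rm)
    upd <- rq_sub(list(n = Tn[act, , drop = FALSE], d = Td[act, , drop = FALSE]), P)
    Tn[act, ] <- upd$n
    Td[act, ] <- upd$d
  }
  list(n = Tn, d = Td)
}

# Bland-rule simplex on a tableau whose last row is the (reduced) cost row
# and last column the rhs.  `ncols` = number of decision columns eligible
# to enter.  Returns status and updated state.
.lp_simplex <- function(Tn, Td, basis, ncols, max_iter = 20000L) {
  m <- nrow(Tn) - 1L
  rhs_col <- ncol(Tn)
  for (iter in seq_len(max_iter)) {
    crn <- Tn[m + 1L, seq_len(ncols)]
    neg <- which(crn < 0)
    if (!length(neg)) {
      return(list(n = Tn, d = Td, basis = basis, status = "optimal"))
    }
    e <- neg[1L]
    pos <- which(Tn[seq_len(m), e] > 0)
    if (!length(pos)) {
      return(list(n = Tn, d = Td, basis = basis, status = "unbounded"))
    }
    # min ratio rhs_i / T[i, e]; ties broken by smallest basis index (Bland)
    best <- NULL
    for (i in pos) {
      ratio <- rq_div(list(n = Tn[i, rhs_col], d = Td[i, rhs_col]),
                      list(n = Tn[i, e], d = Td[i, e]))
      if (is.null(best)) {
        best <- list(i = i, ratio = ratio)
      } else {
        cmp <- rq_cmp(ratio, best$ratio)
        if (cmp < 0 || (cmp == 0 && basis[i] < basis[best$i])) {
          best <- list(i = i, ratio = ratio)
        }
      }
    }
    res <- .lp_pivot(Tn, Td, best$i, e)
    Tn <- res$n
    Td <- res$d
    basis[best$i] <- e
  }
  stop("simplex iteration limit reached", call. = FALSE)
}

#' Solve a linear program in exact rational arithmetic
#'
#' A small two-phase simplex with Bland's rule operating entirely on exact
#' rationals.  All inputs must be exactly rational-representable numbers
#' (bounds may be infinite).  Feasibility, unboundedness and the sign of
#' the optimum are decided exactly — there is no feasibility or optimality
#' tolerance anywhere.
#'
#' @param obj objective coefficient vector (length n).
#' @param mat constraint matrix (rows are constraints), or `NULL` for none.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"="`.
#' @param rhs right-hand side vector.
#' @param lower,upper variable bounds, recycled to length n; may be
#'   `-Inf`/`Inf`.  Defaults: `lower = 0`, `upper = Inf`.
#' @param maximize if `TRUE` maximize `obj`, else minimize.
#' @return a list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), and for optimal solutions `x` (numeric), `x_rq`
#'   (exact rational solution as a numerator/denominator pair),
#'   `objective` and `objective_rq`.
#' @export
lp_exact <- function(obj, mat = NULL, dir = character(), rhs = numeric(),
                     lower = 0, upper = Inf, maximize = FALSE) {
  n0 <- length(obj)
  if (n0 == 0) stop("objective has length zero", call. = FALSE)
  if (is.null(mat)) mat <- matrix(0, 0, n0)
  mat <- as.matrix(mat)
  if (ncol(mat) != n0) stop("ncol(mat) must equal length(obj)", call. = FALSE)
  if (nrow(mat) != length(dir) || nrow(mat) != length(rhs)) {
    stop("dir and rhs must have one entry per row of mat", call. = FALSE)
  }
  if (!all(dir %in% c("<=", ">=", "="))) {
    stop("dir entries must be one of '<=', '>=', '='", call. = FALSE)
  }
  lower <- rep_len(lower, n0)
  upper <- rep_len(upper, n0)
  if (any(lower > upper)) stop("lower bound exceeds upper bound", call. = FALSE)

  m0 <- nrow(mat)
  A0 <- if (m0 > 0) rq_from_num(mat) else list(n = matrix(0, 0, n0), d = matrix(1, 0, n0))
  b0 <- if (m0 > 0) rq_from_num(rhs) else list(n = numeric(0), d = numeric(0))
  c0 <- rq_from_num(if (maximize) -obj else obj)

  # variable substitution to z >= 0
  zcols_n <- list()   # structural columns over the m0 original rows
  zcols_d <- list()
  zcost_n <- numeric(0)
  zcost_d <- numeric(0)
  var_map <- vector("list", n0)
  ub_rows <- list()   # list(z = index, bound = rq scalar)
  for (j in seq_len(n0)) {
    colj <- if (m0 > 0) list(n = A0$n[, j], d = A0$d[, j]) else list(n = numeric(0), d = numeric(0))
    cj <- rq_elt(c0, j)
    if (is.finite(lower[j])) {
      lj <- rq_from_num(lower[j])
      if (lj$n != 0 && m0 > 0) {
        b0 <- rq_sub(b0, rq_mul(colj, list(n = rep(lj$n, m0), d = rep(lj$d, m0))))
      }
      zcols_n[[length(zcols_n) + 1L]] <- colj$n
      zcols_d[[length(zcols_d) + 1L]] <- colj$d
      zcost_n <- c(zcost_n, cj$n)
      zcost_d <- c(zcost_d, cj$d)
      zi <- length(zcols_n)
      var_map[[j]] <- list(kind = "shift", z = zi, const = lj)
      if (is.finite(upper[j])) {
        span <- rq_sub(rq_from_num(upper[j]), lj)
        ub_rows[[length(ub_rows) + 1L]] <- list(z = zi, bound = span)
      }
    } else if (is.finite(upper[j])) {
      uj <- rq_from_num(upper[j])
      if (uj$n != 0 && m0 > 0) {
        b0 <- rq_sub(b0, rq_mul(colj, list(n = rep(uj$n, m0), d = rep(uj$d, m0))))
      }
      zcols_n[[length(zcols_n) + 1L]] <- -colj$n
      zcols_d[[length(zcols_d) + 1L]] <- colj$d
      zcost_n <- c(zcost_n, -cj$n)
      zcost_d <- c(zcost_d, cj$d)
      var_map[[j]] <- list(kind = "neg", z = length(zcols_n), const = uj)
    } else {
      zcols_n[[length(zcols_n) + 1L]] <- colj$n
      zcols_d[[length(zcols_d) + 1L]] <- colj$d
      zcost_n <- c(zcost_n, cj$n)
      zcost_d <- c(zcost_d, cj$d)
      zp <- length(zcols_n)
      zcols_n[[length(zcols_n) + 1L]] <- -colj$n
      zcols_d[[length(zcols_d) + 1L]] <- colj$d
      zcost_n <- c(zcost_n, -cj$n)
      zcost_d <- c(zcost_d, cj$d)
      var_map[[j]] <- list(kind = "split", z = c(zp, zp + 1L))
    }
  }
  nz <- length(zcols_n)

  # assemble rows: original constraints then upper-bound rows
  nub <- length(ub_rows)
  nrows <- m0 + nub
  Mn <- matrix(0, nrows, nz)
  Md <- matrix(1, nrows, nz)
  if (m0 > 0) {
    for (z in seq_len(nz)) {
      Mn[seq_len(m0), z] <- zcols_n[[z]]
      Md[seq_len(m0), z] <- zcols_d[[z]]
    }
  }
  bn <- c(b0$n, numeric(nub))
  bd <- c(b0$d, rep(1, nub))
  rowdir <- c(dir, rep("<=", nub))
  for (k in seq_len(nub)) {
    Mn[m0 + k, ub_rows[[k]]$z] <- 1
    bn[m0 + k] <- ub_rows[[k]]$bound$n
    bd[m0 + k] <- ub_rows[[k]]$bound$d
  }

  # slacks
  nslack <- sum(rowdir != "=")
  Sn <- matrix(0, nrows, nslack)
  Sd <- matrix(1, nrows, nslack)
  si <- 0L
  for (i in seq_len(nrows)) {
    if (rowdir[i] == "=") next
    si <- si + 1L
    Sn[i, si] <- if (rowdir[i] == "<=") 1 else -1
  }
  Fn <- cbind(Mn, Sn)
  Fd <- cbind(Md, Sd)
  # make rhs nonnegative
  for (i in seq_len(nrows)) {
    if (bn[i] < 0) {
      Fn[i, ] <- -Fn[i, ]
      bn[i] <- -bn[i]
    }
  }
  ncols <- nz + nslack
  nart <- nrows
  # tableau: [structural | slack | artificial | rhs], plus cost row
  Tn <- cbind(Fn, diag(1, nrows), bn)
  Td <- cbind(Fd, matrix(1, nrows, nrows), bd)
  basis <- ncols + seq_len(nrows)

  # phase 1 reduced costs: cost 1 on artificials, basics are artificials
  crn <- c(numeric(ncols), rep(1, nart), 0)
  crd <- rep(1, ncols + nart + 1)
  cr <- list(n = crn, d = crd)
  for (i in seq_len(nrows)) {
    cr <- rq_sub(cr, list(n = Tn[i, ], d = Td[i, ]))
  }
  Tn <- rbind(Tn, cr$n)
  Td <- rbind(Td, cr$d)

  if (nrows > 0) {
    res <- .lp_simplex(Tn, Td, basis, ncols + nart)
    if (res$status != "optimal") stop("internal error: phase 1 cannot be unbounded", call. = FALSE)
    Tn <- res$n
    Td <- res$d
    basis <- res$basis
    rhs_col <- ncol(Tn)
    # phase-1 objective = -cost-row rhs entry; infeasible iff > 0
    if (-Tn[nrows + 1L, rhs_col] > 0) {
      return(list(status = "infeasible"))
    }
    # drive remaining artificials out of the basis
    drop_rows <- integer(0)
    for (i in seq_len(nrows)) {
      if (basis[i] <= ncols) next
      piv <- which(Tn[i, seq_len(ncols)] != 0)
      if (length(piv)) {
        res <- .lp_pivot(Tn, Td, i, piv[1L])
        Tn <- res$n
        Td <- res$d
        basis[i] <- piv[1L]
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows)) {
      Tn <- Tn[-drop_rows, , drop = FALSE]
      Td <- Td[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      nrows <- nrows - length(drop_rows)
    }
    # strip artificial columns
    keep <- c(seq_len(ncols), ncols + nart + 1L)
    Tn <- Tn[, keep, drop = FALSE]
    Td <- Td[, keep, drop = FALSE]
  } else {
    Tn <- Tn[, c(seq_len(ncols), ncols + nart + 1L), drop = FALSE]
    Td <- Td[, c(seq_len(ncols), ncols + nart + 1L), drop = FALSE]
    basis <- integer(0)
  }

  # phase 2 cost row from the transformed objective
  cost <- rq_canon(c(zcost_n, numeric(nslack), 0), c(zcost_d, rep(1, nslack), 1))
  cr <- cost
  for (i in seq_len(nrows)) {
    cb <- list(n = cost$n[basis[i]], d = cost$d[basis[i]])
    if (cb$n != 0) {
      K <- ncol(Tn)
      cr <- rq_sub(cr, rq_mul(list(n = rep(cb$n, K), d = rep(cb$d, K)),
                              list(n = Tn[i, ], d = Td[i, ])))
    }
  }
  Tn[nrow(Tn), ] <- 0
  Td[nrow(Td), ] <- 1
  Tn <- rbind(Tn[seq_len(nrows), , drop = FALSE], cr$n)
  Td <- rbind(Td[seq_len(nrows), , drop = FALSE], cr$d)

  res <- .lp_simplex(Tn, Td, basis, ncols)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  Tn <- res$n
  Td <- res$d
  basis <- res$basis
  rhs_col <- ncol(Tn)

  zn <- numeric(nz + nslack)
  zd <- rep(1, nz + nslack)
  for (i in seq_len(nrows)) {
    zn[basis[i]] <- Tn[i, rhs_col]
    zd[basis[i]] <- Td[i, rhs_col]
  }
  xn <- numeric(n0)
  xd <- rep(1, n0)
  for (j in seq_len(n0)) {
    vm <- var_map[[j]]
    val <- switch(vm$kind,
      shift = rq_add(list(n = zn[vm$z], d = zd[vm$z]), vm$const),
      neg = rq_sub(vm$const, list(n = zn[vm$z], d = zd[vm$z])),
      split = rq_sub(list(n = zn[vm$z[1]], d = zd[vm$z[1]]),
                     list(n = zn[vm$z[2]], d = zd[vm$z[2]])))
    xn[j] <- val$n
    xd[j] <- val$d
  }
  x_rq <- rq_canon(xn, xd)
  obj_rq <- rq_dot(rq_from_num(obj), x_rq)
  list(status = "optimal",
       x = rq_to_num(x_rq),
       x_rq = x_rq,
       objective = rq_to_num(obj_rq),
       objective_rq = obj_rq)
}
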