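#' @importFrom boot simplex
NULL

#' Solve a bounded-variable linear program
#'
#' Internal workhorse behind the solver-backend abstraction. Solves
#' \deqn{\max / \min \; c^\top v \quad \mathrm{s.t.}\quad
#'   A_{eq} v = b_{eq},\; A_{in} v \le b_{in},\; lb \le v \le ub}
#' with all bounds finite. Variables are shifted to the non-negative orthant,
#' upper bounds become inequality rows, and rows with negative right-hand
#' sides are normalised (equalities negated, "<=" rows moved to the ">=" block)
#' so the problem lands in the standard form expected by the two-phase simplex
#' backend.
#'
#' @param obj objective coefficients, length n.
#' @param lb,ub finite variable bounds, length n, `lb <= ub`.
#' @param Aeq,beq equality block (matrix m_eq x n, vector m_eq), or NULL.
#' @param Ain,bin inequality block `Ain v <= bin`, or NULL.
#' @param maximize logical; maximize (default) or minimize.
#' @param eps pivot tolerance passed to the backend.
#' @param n_iter iteration cap; default scales with problem size.
#' @return list with `status` ("optimal", "infeasible", "maxiter"),
#'   `solution` (length n, on the original scale) and `objective`.
#' @keywords internal
lp_solve <- function(obj, lb, ub, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                     maximize = TRUE, eps = 1e-9, n_iter = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    stop("lp_solve: lower bound exceeds upper bound")
  if (!is.null(Aeq)) Aeq <- as.matrix(Aeq)
  if (!is.null(Ain)) Ain <- as.matrix(Ain)

  # presolve: a zero-rhs equality row whose terms are all single-signed can
  # only be satisfied with every participating variable at zero (dead-end
  # metabolites, e.g. downstream of a disabled reaction); fixing them up
  # front also removes degenerate vertices the simplex backend dislikes
  if (!is.null(Aeq) && length(beq)) {
    repeat {
      changed <- FALSE
      for (r in seq_along(beq)) {
        if (abs(beq[r]) > 1e-15) next
        a <- Aeq[r, ]
        nz <- which(a != 0 & !(lb == 0 & ub == 0))
        if (!length(nz)) next
        tmin <- ifelse(a[nz] > 0, a[nz] * lb[nz], a[nz] * ub[nz])
        tmax <- ifelse(a[nz] > 0, a[nz] * ub[nz], a[nz] * lb[nz])
        force0 <- (all(tmin >= 0) && any(tmax > 0)) ||
                  (all(tmax <= 0) && any(tmin < 0))
        if (!force0) next
        if (any(lb[nz] > 1e-14) || any(ub[nz] < -1e-14)) {
          sol <- rep(NA_real_, n)
          return(list(status = "infeasible", solution = sol,
                      objective = NA_real_))
        }
        lb[nz] <- 0; ub[nz] <- 0
        changed <- TRUE
      }
      if (!changed) break
    }
  }

  # variables fixed by their bounds are substituted out
  fixed <- (ub - lb) <= 1e-14
  free <- which(!fixed)
  vfix <- lb
  vfix[free] <- 0

  if (length(free) == 0L) {
    sol <- lb
    feas <- TRUE
    if (!is.null(Aeq) && length(beq))
      feas <- feas && max(abs(Aeq %*% sol - beq)) <= 1e-7
    if (!is.null(Ain) && length(bin))
      feas <- feas && max(Ain %*% sol - bin) <= 1e-7
    return(list(status = if (feas) "optimal" else "infeasible",
                solution = sol, objective = sum(obj * sol)))
  }

  # shift x = v - lb on the free variables; fold fixed variables into the rhs
  shift <- lb
  shift[fixed] <- lb[fixed]
  o <- obj[free]
  const <- sum(obj * shift)

  adjust_rhs <- function(A, b) {
    if (is.null(A) || length(b) == 0L) return(NULL)
    list(A = A[, free, drop = FALSE], b = as.numeric(b - A %*% shift))
  }
  eqb <- adjust_rhs(Aeq, beq)
  inb <- adjust_rhs(Ain, bin)

  ubx <- ub[free] - lb[free]

  # A1: "<=" rows with b >= 0 (includes variable upper bounds)
  # A2: ">=" rows with b >= 0 (negated "<=" rows that had b < 0)
  # A3: "=" rows, negated where b < 0
  A1 <- diag(length(free))
  b1 <- ubx
  if (!is.null(inb)) {
    neg <- inb$b < 0
    if (any(!neg)) {
      A1 <- rbind(inb$A[!neg, , drop = FALSE], A1)
      b1 <- c(inb$b[!neg], b1)
    }
    if (any(neg)) {
      A2 <- -inb$A[neg, , drop = FALSE]
      b2 <- -inb$b[neg]
    } else {
      A2 <- NULL; b2 <- NULL
    }
  } else {
    A2 <- NULL; b2 <- NULL
  }
  if (!is.null(eqb)) {
    neg <- eqb$b < 0
    A3 <- eqb$A
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3 <- abs(eqb$b)
  } else {
    A3 <- NULL; b3 <- NULL
  }

  m <- nrow(A1) + NROW(A2) + NROW(A3)
  if (is.null(n_iter)) n_iter <- max(200L, 50L * (length(free) + m))

  out <- try(boot::simplex(a = o, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                           A3 = A3, b3 = b3, maxi = maximize,
                           n.iter = n_iter, eps = eps), silent = TRUE)
  if (inherits(out, "try-error")) {
    # the backend's two-phase bookkeeping can fail on degenerate vertices
    # where an inequality with zero rhs binds; nudging those rows by an
    # amount far below every reported tolerance restores a valid pivot path
    out <- try(boot::simplex(a = o, A1 = A1, b1 = b1 + 1e-11,
                             A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                             maxi = maximize, n.iter = n_iter, eps = eps),
               silent = TRUE)
    if (inherits(out, "try-error"))
      out <- boot::simplex(a = o, A1 = A1, b1 = b1 + 1e-11, A2 = A2,
                           b2 = if (is.null(b2)) NULL else b2 + 1e-11,
                           A3 = A3, b3 = b3 + 1e-11, maxi = maximize,
                           n.iter = n_iter, eps = eps)
  }

  status <- switch(as.character(out$solved),
                   "1" = "optimal", "0" = "maxiter", "-1" = "infeasible",
                   "unknown")
  sol <- vfix
  if (status == "optimal") {
    x <- as.numeric(out$soln)
    # clip round-off outside the box
    x <- pmin(pmax(x, 0), ubx)
    sol[free] <- x + lb[free]
  } else {
    sol[] <- NA_real_
  }
  list(status = status, solution = sol,
       objective = if (status == "optimal") sum(obj * sol) else NA_real_)
}
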