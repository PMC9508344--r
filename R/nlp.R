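# Sparse primal-dual log-barrier interior-point solver for nonlinear programs
#
#   min f(x)  s.t.  c(x) = 0,  l <= x <= u
#
# with every variable bounded (the transcriber scales all variables to lie in
# [-1, 1], so finite bounds always exist). The barrier parameter follows a
# monotone reduction schedule; search directions come from a regularized
# primal-dual KKT system solved with sparse LU (Matrix); globalization is a
# backtracking line search on an l1-penalty barrier merit function with a
# fraction-to-the-boundary rule. Convergence is declared on the scaled KKT
# error, by default at the 1e-3 tolerance customary for collocation NLPs of
# this kind.

#' Interior-point solution of a bounded, equality-constrained NLP
#'
#' @param x0 initial guess.
#' @param lower,upper finite variable bounds; entries with
#'   `upper - lower < 1e-12` are treated as fixed variables and eliminated.
#' @param obj function(x) returning `list(f, g, H)` with sparse Hessian `H`
#'   (of the objective; constraint curvature is not required).
#' @param con optional function(x) returning the equality constraint values.
#' @param jac optional function(x) returning the sparse constraint Jacobian.
#' @param hess_con optional function(x, lambda) returning the sparse
#'   constraint-curvature Hessian contribution `sum_r lambda_r Hess(c_r)`
#'   (used where constraint bilinearity matters, e.g. a free time horizon).
#' @param control list of options: `tol` (KKT tolerance, default 1e-3),
#'   `mu_init`, `max_iter`, `verbose`, `log_file`, `ls_mode` ("merit" for the
#'   l1 exact-penalty line search, "filter" for a filter acceptance).
#' @return list with `x`, `f`, `status` ("solved", "max_iter" or "failed"),
#'   `iterations`, `kkt_error`, `lambda`.
#' @export
solve_ipnlp <- function(x0, lower, upper, obj, con = NULL, jac = NULL,
                        hess_con = NULL, control = list()) {
  ct <- utils::modifyList(list(tol = 1e-3, mu_init = 1e-2, max_iter = 400,
                               verbose = FALSE, log_file = NULL,
                               kappa_eps = 10, tau_min = 0.99, step_cap = 0.5,
                               ls_mode = "merit", feas_tol = 5e-3), control)
  n_all <- length(x0)
  stopifnot(length(lower) == n_all, length(upper) == n_all,
            all(is.finite(lower)), all(is.finite(upper)), all(upper >= lower))
  fixed <- which(upper - lower < 1e-12)
  free <- setdiff(seq_len(n_all), fixed)
  xfix <- (lower + upper) / 2
  expand <- function(xf) { z <- xfix; z[free] <- xf; z }
  obj_f <- function(xf) {
    o <- obj(expand(xf))
    list(f = o$f, g = o$g[free], H = o$H[free, free, drop = FALSE])
  }
  has_con <- !is.null(con)
  con_f <- if (has_con) function(xf) con(expand(xf)) else function(xf) numeric(0)
  jac_f <- if (has_con) function(xf) jac(expand(xf))[, free, drop = FALSE] else NULL

  l <- lower[free]; u <- upper[free]
  n <- length(l)
  rng <- u - l
  pad <- pmin(1e-2 * rng, 1e-4 + 0 * rng)
  x <- pmin(pmax(x0[free], l + pad), u - pad)

  cv <- con_f(x)
  m <- length(cv)
  J <- if (has_con) jac_f(x) else NULL
  o <- obj_f(x)
  lam <- numeric(m)
  mu <- ct$mu_init
  zl <- pmax(mu / (x - l), 1e-8)
  zu <- pmax(mu / (u - x), 1e-8)
  delta <- 0
  nu <- 1 # merit penalty
  logf <- if (!is.null(ct$log_file)) file(ct$log_file, "w") else NULL
  on.exit(if (!is.null(logf)) close(logf))
  note <- function(...) {
    msg <- sprintf(...)
    if (ct$verbose) message(msg)
    if (!is.null(logf)) writeLines(msg, logf)
  }

  kkt_error <- function(g, Jm, cv, lam, zl, zu, x, mu) {
    dual <- g - zl + zu
    if (m > 0) dual <- dual + as.numeric(Matrix::crossprod(Jm, lam))
    sd <- max(1, (sum(abs(lam)) + sum(zl) + sum(zu)) / max(1, (m + 2 * n))) / 1
    max(max(abs(dual)) / sd,
        if (m > 0) max(abs(cv)) else 0,
        max(abs(zl * (x - l) - mu)),
        max(abs(zu * (u - x) - mu)))
  }

  barrier_merit <- function(x, fv, cv, mu, nu) {
    fv - mu * sum(log(x - l)) - mu * sum(log(u - x)) + nu * sum(abs(cv))
  }

  status <- "max_iter"
  iter <- 0
  E0 <- Inf
  alpha_last <- NA_real_
  ftb_last <- NA_real_
  filt <- matrix(c(1e4 * max(1, sum(abs(cv))), -Inf), 1, 2)
  for (iter in seq_len(ct$max_iter)) {
    E0 <- kkt_error(o$g, J, cv, lam, zl, zu, x, 0)
    Emu <- kkt_error(o$g, J, cv, lam, zl, zu, x, mu)
    note("it %3d  f=%.8e  kkt=%.2e  mu=%.1e  |c|=%.2e  delta=%.1e  alpha=%.2e  ftb=%.2e",
         iter, o$f, E0, mu, if (m > 0) max(abs(cv)) else 0, delta, alpha_last, ftb_last)
    if (E0 <= ct$tol) { status <- "solved"; break }
    if (Emu <= ct$kappa_eps * mu && mu > ct$tol / 20) {
      mu <- max(ct$tol / 20, min(0.2 * mu, mu^1.5))
      zl <- pmin(pmax(zl, mu / (2 * rng)), 1e8)
      zu <- pmin(pmax(zu, mu / (2 * rng)), 1e8)
      filt <- filt[1, , drop = FALSE] # restart the filter per barrier problem
      next
    }

    Sig <- zl / (x - l) + zu / (u - x)
    grad_phi <- o$g - mu / (x - l) + mu / (u - x)
    Hc <- if (!is.null(hess_con) && m > 0) {
      hess_con(expand(x), lam)[free, free, drop = FALSE]
    } else NULL
    solved <- FALSE
    for (reg_try in 1:12) {
      W <- o$H + Matrix::Diagonal(n, Sig + delta)
      if (!is.null(Hc)) W <- W + Hc
      if (m > 0) {
        KKT <- rbind(cbind(W, Matrix::t(J)),
                     cbind(J, Matrix::Diagonal(m, -max(delta * 1e-2, 1e-10))))
        rhs <- c(-grad_phi, -cv)
      } else {
        KKT <- W
        rhs <- -grad_phi
      }
      sol <- tryCatch(Matrix::solve(KKT, rhs), error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        dx <- sol[seq_len(n)]
        lam_new <- if (m > 0) sol[n + seq_len(m)] else numeric(0)
        # require a descent-ish primal direction for the merit function
        dphi <- sum(grad_phi * dx)
        if (dphi <= 0 || (m > 0 && max(abs(cv)) > 1e-8)) { solved <- TRUE; break }
      }
      delta <- if (delta == 0) 1e-6 else delta * 10
      if (delta > 1e10) break
    }
    if (!solved) { status <- "failed"; break }
    # infinity-norm trust cap: stiff (contact-grade) constraint curvature is
    # not in the Hessian model, so long steps are unreliable
    stepmax <- max(abs(dx))
    if (stepmax > ct$step_cap) {
      shrink <- ct$step_cap / stepmax
      dx <- dx * shrink
      if (m > 0) lam_new <- lam + shrink * (lam_new - lam)
    }

    dzl <- (mu - zl * (x - l) - zl * dx) / (x - l)
    dzu <- (mu - zu * (u - x) + zu * dx) / (u - x)
    tau <- max(ct$tau_min, 1 - mu)
    step_to <- function(v, dv, lo) {
      bad <- dv < 0
      if (!any(bad)) return(1)
      min(1, min(tau * (v[bad] - lo[bad]) / (-dv[bad])))
    }
    a_pri <- min(step_to(x, dx, l), step_to(-x, -dx, -u))
    a_dual <- min(step_to(zl, dzl, 0 * zl), step_to(zu, dzu, 0 * zu))
    ftb_last <- a_pri

    # Filter line search: a trial is acceptable when it is not dominated by
    # any filter entry and makes progress in either the barrier objective or
    # the constraint violation; objective-type steps satisfy an Armijo
    # condition on the barrier function, violation-reducing steps augment the
    # filter. A second-order correction absorbs constraint curvature at the
    # first rejection.
    theta_c <- sum(abs(cv))
    phi_bar <- function(xv, fv) {
      fv - mu * sum(log(xv - l)) - mu * sum(log(u - xv))
    }
    phi_c <- phi_bar(x, o$f)
    dphi <- sum(grad_phi * dx)
    acceptable <- function(tht, pht) {
      all(tht <= (1 - 1e-5) * filt[, 1] | pht <= filt[, 2] - 1e-5 * filt[, 1])
    }
    try_point <- function(xt) {
      ot_f <- tryCatch(obj(expand(xt))$f, error = function(e) NA_real_)
      cvt <- tryCatch(con_f(xt), error = function(e) rep(NA_real_, m))
      if (!is.finite(ot_f) || anyNA(cvt)) return(NULL)
      list(x = xt, f = ot_f, cv = cvt, theta = sum(abs(cvt)),
           phi = phi_bar(xt, ot_f))
    }
    if (ct$ls_mode == "merit") {
      # l1 exact-penalty acceptance (monotone, conservative)
      if (m > 0) {
        nu_req <- 1.2 * max(abs(lam_new)) + 1e-3
        if (nu < nu_req) nu <- nu_req
      }
      merit_c <- phi_c + nu * theta_c
      dmer <- dphi - nu * theta_c
      accept_rules <- function(tp, alpha) {
        if (is.null(tp)) return(FALSE)
        (tp$phi + nu * tp$theta) <=
          merit_c + 1e-4 * alpha * min(dmer, 0) + 1e-12 * abs(merit_c)
      }
    } else {
      accept_rules <- function(tp, alpha) {
        if (is.null(tp) || !acceptable(tp$theta, tp$phi)) return(FALSE)
        f_type <- dphi < 0 && alpha * (-dphi) > theta_c^1.1
        if (f_type) {
          tp$phi <= phi_c + 1e-4 * alpha * dphi
        } else if (tp$theta <= (1 - 1e-5) * theta_c ||
                   tp$phi <= phi_c - 1e-5 * theta_c) {
          filt <<- rbind(filt, c((1 - 1e-5) * theta_c, phi_c - 1e-5 * theta_c))
          TRUE
        } else FALSE
      }
    }
    alpha <- a_pri
    ok <- FALSE
    soc_done <- FALSE
    accepted <- NULL
    for (ls in 1:30) {
      tp <- try_point(x + alpha * dx)
      if (accept_rules(tp, alpha)) { accepted <- tp; break }
      if (!soc_done && !is.null(tp) && m > 0 && ls == 1) {
        soc_done <- TRUE
        sol2 <- tryCatch(Matrix::solve(KKT, c(numeric(n), -tp$cv)),
                         error = function(e) NULL)
        if (!is.null(sol2) && all(is.finite(sol2))) {
          dx2 <- sol2[seq_len(n)]
          a2 <- min(step_to(tp$x, dx2, l), step_to(-tp$x, -dx2, -u))
          tp2 <- try_point(tp$x + a2 * dx2)
          if (accept_rules(tp2, alpha)) { accepted <- tp2; break }
        }
      }
      alpha <- alpha / 2
    }
    ok <- !is.null(accepted)
    if (!ok) {
      delta <- if (delta == 0) 1e-6 else delta * 10
      if (delta > 1e10) { status <- "failed"; break }
      next
    }
    alpha_last <- alpha
    x <- accepted$x
    if (m > 0) lam <- lam + alpha * (lam_new - lam)
    zl <- zl + a_dual * dzl
    zu <- zu + a_dual * dzu
    # keep multipliers in a primal-dual safeguard box
    zl <- pmin(pmax(zl, mu / (1e10 * (x - l))), 1e10 * mu / (x - l) + 1)
    zu <- pmin(pmax(zu, mu / (1e10 * (u - x))), 1e10 * mu / (u - x) + 1)
    delta <- delta / 4
    if (delta < 1e-10) delta <- 0
    o <- obj_f(x)
    cv <- accepted$cv
    if (has_con) J <- jac_f(x)
  }

  if (status == "max_iter" && m > 0 && max(abs(cv)) <= ct$feas_tol) {
    # objective progress has plateaued but the iterate satisfies the equality
    # constraints to the feasibility tolerance: usable as a solution
    status <- "stalled"
  }
  note("status=%s iterations=%d kkt=%.3e", status, iter, E0)
  xfull <- expand(x)
  list(x = xfull, f = obj(xfull)$f, status = status, iterations = iter,
       kkt_error = E0, lambda = lam, mu = mu)
}
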