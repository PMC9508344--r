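# Transcription of an ocp_def into a scaled NLP and its solution.

#' Transcribe an optimal control problem into a scaled NLP
#'
#' Assembles decision-variable bounds and initial guess, the constant linear
#' constraint block (state continuity and, for fixed-horizon linear dynamics,
#' the collocation equations), the nonlinear constraint block (collocation
#' equations under a free final time or nonlinear dynamics, and path
#' constraints with bounded slacks for inequality rows), and the quadratic
#' quadrature objective -- all affinely scaled so every variable lies in
#' [-1, 1].
#'
#' @param ocp an [define_ocp()] object.
#' @return an NLP structure (list) with layout, bounds, guess, objective and
#'   constraint callbacks; input to [solve_ocp()].
#' @export
transcribe <- function(ocp) {
  layout <- ocp_layout(ocp)
  N <- layout$N; d <- layout$d; nx <- layout$nx; nu <- layout$nu
  D <- layout$D

  # ---- bounds and guess over core variables -------------------------------
  lb <- numeric(layout$nz_core); ub <- lb
  for (dof in seq_len(nx)) {
    lb[layout$ix[, , dof]] <- ocp$x_lb[dof]
    ub[layout$ix[, , dof]] <- ocp$x_ub[dof]
  }
  for (j in seq_len(nu)) {
    lb[layout$iu[, j]] <- ocp$u_lb[j]
    ub[layout$iu[, j]] <- ocp$u_ub[j]
  }
  for (fx in ocp$x_fix) {
    id <- layout$ix[fx$i, fx$k + 1, fx$dof]
    lb[id] <- ub[id] <- fx$value
  }
  for (wd in ocp$x_window) {
    id <- layout$ix[wd$i, wd$k + 1, wd$dof]
    lb[id] <- max(lb[id], wd$lb)
    ub[id] <- min(ub[id], wd$ub)
    if (lb[id] > ub[id]) stop("empty state window at dof ", wd$dof)
  }
  if (layout$free_tf) { lb[layout$itf] <- ocp$tf$lower; ub[layout$itf] <- ocp$tf$upper }

  # guesses
  z0 <- (lb + ub) / 2
  tf_guess <- if (layout$free_tf) {
    if (!is.null(ocp$tf$guess)) ocp$tf$guess else ocp$tf$upper
  } else ocp$tf
  if (!is.null(ocp$x_guess)) {
    for (i in seq_len(N)) for (k in 0:d) {
      tn <- layout$tau_grid[i, k + 1]
      g <- if (is.function(ocp$x_guess)) drop(ocp$x_guess(tn)) else ocp$x_guess
      z0[layout$ix[i, k + 1, ]] <- g
    }
  }
  if (!is.null(ocp$u_guess)) {
    for (ci in seq_len(layout$n_cnodes)) {
      tn <- min((ci - 1) / N, 1)
      g <- if (is.function(ocp$u_guess)) drop(ocp$u_guess(tn)) else ocp$u_guess
      z0[layout$iu[ci, ]] <- g
    }
  }
  if (layout$free_tf) z0[layout$itf] <- tf_guess

  # ---- path-constraint slacks --------------------------------------------
  npc_pts <- N + as.integer(ocp$path_terminal)
  ineq_rows <- if (ocp$npath > 0) which(ocp$path_ub > ocp$path_lb) else integer(0)
  nslack_per <- length(ineq_rows)
  nslack <- npc_pts * nslack_per
  islack <- if (nslack > 0) {
    matrix(layout$nz_core + seq_len(nslack), nrow = npc_pts, byrow = TRUE)
  } else NULL
  nz <- layout$nz_core + nslack
  if (nslack > 0) {
    # slack variables in point-major order, matching islack's rows
    lb <- c(lb, rep(ocp$path_lb[ineq_rows], times = npc_pts))
    ub <- c(ub, rep(ocp$path_ub[ineq_rows], times = npc_pts))
    z0 <- c(z0, (utils::tail(lb, nslack) + utils::tail(ub, nslack)) / 2)
  }

  # ---- variable scaling ---------------------------------------------------
  mid <- (lb + ub) / 2
  half <- (ub - lb) / 2
  s_eff <- ifelse(half < 1e-12, 1, half)
  Svar <- Matrix::Diagonal(nz, s_eff)
  lb_s <- ifelse(half < 1e-12, mid, -1)
  ub_s <- ifelse(half < 1e-12, mid, 1)
  # in scaled space fixed variables carry their value so the solver pins them
  lb_s[half < 1e-12] <- 0; ub_s[half < 1e-12] <- 0
  mid[half < 1e-12] <- (lb + ub)[half < 1e-12] / 2
  z0_s <- ifelse(half < 1e-12, 0, (pmin(pmax(z0, lb), ub) - mid) / s_eff)
  unscale <- function(zs) mid + s_eff * zs

  # row scale for dynamics/continuity rows of each state dof
  sx <- vapply(seq_len(nx), function(dof) {
    max(1e-6, max(abs(ocp$x_lb[dof]), abs(ocp$x_ub[dof])))
  }, numeric(1))

  # ---- constant linear constraint block ----------------------------------
  trip_i <- integer(0); trip_j <- integer(0); trip_v <- numeric(0)
  b_lin <- numeric(0)
  row0 <- 0L
  add_trip <- function(r, c, v) {
    trip_i <<- c(trip_i, r); trip_j <<- c(trip_j, c); trip_v <<- c(trip_v, v)
  }
  # continuity: x_i^END - x_{i+1}^0 = 0
  for (i in seq_len(N - 1)) {
    for (dof in seq_len(nx)) {
      row0 <- row0 + 1L
      add_trip(row0, layout$ix[i, d + 1, dof], 1 / sx[dof])
      add_trip(row0, layout$ix[i + 1, 1, dof], -1 / sx[dof])
      b_lin <- c(b_lin, 0)
    }
  }
  dyn_is_linear_fixed <- !layout$free_tf && !is.null(ocp$linear_dyn)
  if (dyn_is_linear_fixed) {
    h <- tf_guess / N
    Ad <- ocp$linear_dyn$A; Bd <- ocp$linear_dyn$B
    for (i in seq_len(N)) for (k in seq_len(d)) {
      cc <- control_coef(layout, i, k)
      for (dof in seq_len(nx)) {
        row0 <- row0 + 1L
        for (jn in 0:d) add_trip(row0, layout$ix[i, jn + 1, dof], D[k, jn + 1] / sx[dof])
        arow <- Ad[dof, ]
        for (j2 in which(arow != 0)) {
          add_trip(row0, layout$ix[i, k + 1, j2], -h * arow[j2] / sx[dof])
        }
        brow <- Bd[dof, ]
        for (j2 in which(brow != 0)) for (cn in seq_along(cc$nodes)) {
          add_trip(row0, layout$iu[cc$nodes[cn], j2], -h * brow[j2] * cc$coef[cn] / sx[dof])
        }
        b_lin <- c(b_lin, 0)
      }
    }
  }
  A_lin <- if (row0 > 0) {
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_v, dims = c(row0, nz))
  } else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(0, nz))
  A_lin_s <- A_lin %*% Svar
  b_lin_s <- b_lin - as.numeric(A_lin %*% mid)

  # ---- nonlinear constraint block ----------------------------------------
  # precomputed index matrices for batched evaluation
  dyn_nonconst <- !dyn_is_linear_fixed
  if (dyn_nonconst) {
    # rows stacked (i, k) point-major, dof within
    Xc_idx <- matrix(0L, N * d, nx)
    Dpart_trip <- list(i = integer(0), j = integer(0), v = numeric(0))
    pt <- 0L
    for (i in seq_len(N)) for (k in seq_len(d)) {
      pt <- pt + 1L
      Xc_idx[pt, ] <- layout$ix[i, k + 1, ]
      for (dof in seq_len(nx)) {
        r <- (pt - 1L) * nx + dof
        for (jn in 0:d) {
          Dpart_trip$i <- c(Dpart_trip$i, r)
          Dpart_trip$j <- c(Dpart_trip$j, layout$ix[i, jn + 1, dof])
          Dpart_trip$v <- c(Dpart_trip$v, D[k, jn + 1] / sx[dof])
        }
      }
    }
    A_D <- Matrix::sparseMatrix(i = Dpart_trip$i, j = Dpart_trip$j, x = Dpart_trip$v,
                                dims = c(N * d * nx, nz))
    # control interpolation at collocation points
    Uc_map <- vector("list", N * d)
    pt <- 0L
    for (i in seq_len(N)) for (k in seq_len(d)) {
      pt <- pt + 1L
      Uc_map[[pt]] <- control_coef(layout, i, k)
    }
    tq <- as.vector(t(layout$tau_grid[, -1, drop = FALSE])) # normalized times, point-major
    eval_dyn_inputs <- function(z) {
      Xc <- matrix(z[Xc_idx], N * d, nx)
      Uc <- matrix(0, N * d, nu)
      for (p in seq_len(N * d)) {
        cc <- Uc_map[[p]]
        for (cn in seq_along(cc$nodes)) {
          Uc[p, ] <- Uc[p, ] + cc$coef[cn] * z[layout$iu[cc$nodes[cn], ]]
        }
      }
      list(Xc = Xc, Uc = Uc, tq = tq)
    }
    dyn_fun <- if (!is.null(ocp$linear_dyn)) {
      function(X, U, t) X %*% t(ocp$linear_dyn$A) + U %*% t(ocp$linear_dyn$B)
    } else ocp$dyn
  }
  has_path <- ocp$npath > 0
  if (has_path) {
    pc_i <- seq_len(npc_pts)
    Xs_idx <- matrix(0L, npc_pts, nx)
    Us_idx <- matrix(0L, npc_pts, nu)
    for (p in seq_len(npc_pts)) {
      if (p <= N) {
        Xs_idx[p, ] <- layout$ix[p, 1, ]
        Us_idx[p, ] <- layout$iu[p, ]
      } else {
        Xs_idx[p, ] <- layout$ix[N, d + 1, ]
        Us_idx[p, ] <- layout$iu[min(layout$n_cnodes, N + 1), ]
      }
    }
    ts_norm <- c((seq_len(N) - 1) / N, if (ocp$path_terminal) 1)
  }

  con_nl <- function(z) {
    out <- numeric(0)
    tf_cur <- if (layout$free_tf) z[layout$itf] else tf_guess
    if (dyn_nonconst) {
      ins <- eval_dyn_inputs(z)
      f <- dyn_fun(ins$Xc, ins$Uc, ins$tq * tf_cur)
      # rows are (i, k)-major with dof fastest within a point; scaled by sx
      fscaled <- sweep(f, 2, sx, "/")
      res <- as.numeric(A_D %*% z) - (tf_cur / N) * as.vector(t(fscaled))
      out <- c(out, res)
    }
    if (has_path) {
      Xs <- matrix(z[Xs_idx], npc_pts, nx)
      Us <- matrix(z[Us_idx], npc_pts, nu)
      pv <- ocp$path(Xs, Us, ts_norm * tf_cur)
      pv <- sweep(pv, 2, ocp$path_scale, "/")
      if (nslack > 0) {
        pv[, ineq_rows] <- pv[, ineq_rows] -
          matrix(z[islack], npc_pts, nslack_per) / rep(ocp$path_scale[ineq_rows], each = npc_pts)
      }
      out <- c(out, as.vector(t(pv)))
    }
    out
  }

  jac_nl <- function(z) {
    blocks <- list()
    tf_cur <- if (layout$free_tf) z[layout$itf] else tf_guess
    if (dyn_nonconst) {
      ins <- eval_dyn_inputs(z)
      f <- dyn_fun(ins$Xc, ins$Uc, ins$tq * tf_cur)
      npts <- N * d
      ti <- integer(0); tj <- integer(0); tv <- numeric(0)
      # analytic for linear dynamics, finite differences otherwise
      if (!is.null(ocp$linear_dyn)) {
        dfdX <- lapply(seq_len(nx), function(s) {
          matrix(ocp$linear_dyn$A[, s], npts, nx, byrow = TRUE)
        })
        dfdU <- lapply(seq_len(nu), function(s) {
          matrix(ocp$linear_dyn$B[, s], npts, nx, byrow = TRUE)
        })
      } else {
        hs <- 1e-6
        dfdX <- lapply(seq_len(nx), function(s) {
          Xp <- ins$Xc; Xp[, s] <- Xp[, s] + hs
          Xm <- ins$Xc; Xm[, s] <- Xm[, s] - hs
          (dyn_fun(Xp, ins$Uc, ins$tq * tf_cur) - dyn_fun(Xm, ins$Uc, ins$tq * tf_cur)) / (2 * hs)
        })
        dfdU <- lapply(seq_len(nu), function(s) {
          Up <- ins$Uc; Up[, s] <- Up[, s] + hs
          Um <- ins$Uc; Um[, s] <- Um[, s] - hs
          (dyn_fun(ins$Xc, Up, ins$tq * tf_cur) - dyn_fun(ins$Xc, Um, ins$tq * tf_cur)) / (2 * hs)
        })
      }
      for (p in seq_len(npts)) {
        rows <- (p - 1L) * nx + seq_len(nx)
        for (s in seq_len(nx)) {
          col <- Xc_idx[p, s]
          val <- -(tf_cur / N) * dfdX[[s]][p, ] / sx
          nzr <- which(val != 0)
          ti <- c(ti, rows[nzr]); tj <- c(tj, rep(col, length(nzr))); tv <- c(tv, val[nzr])
        }
        cc <- Uc_map[[p]]
        for (s in seq_len(nu)) {
          val <- -(tf_cur / N) * dfdU[[s]][p, ] / sx
          nzr <- which(val != 0)
          for (cn in seq_along(cc$nodes)) {
            col <- layout$iu[cc$nodes[cn], s]
            ti <- c(ti, rows[nzr]); tj <- c(tj, rep(col, length(nzr)))
            tv <- c(tv, cc$coef[cn] * val[nzr])
          }
        }
        if (layout$free_tf) {
          val <- -(1 / N) * f[p, ] / sx
          nzr <- which(val != 0)
          ti <- c(ti, rows[nzr]); tj <- c(tj, rep(layout$itf, length(nzr))); tv <- c(tv, val[nzr])
        }
      }
      Jd <- A_D + Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(npts * nx, nz))
      blocks <- c(blocks, list(Jd))
    }
    if (has_path) {
      Xs <- matrix(z[Xs_idx], npc_pts, nx)
      Us <- matrix(z[Us_idx], npc_pts, nu)
      tsec <- ts_norm * tf_cur
      p0 <- ocp$path(Xs, Us, tsec)
      ti <- integer(0); tj <- integer(0); tv <- numeric(0)
      np <- ocp$npath
      for (s in seq_len(nx)) {
        hs <- 1e-6 * max(1, s_eff[Xs_idx[1, s]])
        Xp <- Xs; Xp[, s] <- Xp[, s] + hs
        Xm <- Xs; Xm[, s] <- Xm[, s] - hs
        dP <- (ocp$path(Xp, Us, tsec) - ocp$path(Xm, Us, tsec)) / (2 * hs)
        dP <- sweep(dP, 2, ocp$path_scale, "/")
        for (p in seq_len(npc_pts)) {
          rows <- (p - 1L) * np + seq_len(np)
          val <- dP[p, ]
          nzr <- which(abs(val) > 1e-14)
          ti <- c(ti, rows[nzr]); tj <- c(tj, rep(Xs_idx[p, s], length(nzr))); tv <- c(tv, val[nzr])
        }
      }
      for (s in seq_len(nu)) {
        hs <- 1e-6 * max(1, s_eff[Us_idx[1, s]])
        Up <- Us; Up[, s] <- Up[, s] + hs
        Um <- Us; Um[, s] <- Um[, s] - hs
        dP <- (ocp$path(Xs, Up, tsec) - ocp$path(Xs, Um, tsec)) / (2 * hs)
        dP <- sweep(dP, 2, ocp$path_scale, "/")
        for (p in seq_len(npc_pts)) {
          rows <- (p - 1L) * np + seq_len(np)
          val <- dP[p, ]
          nzr <- which(abs(val) > 1e-14)
          ti <- c(ti, rows[nzr]); tj <- c(tj, rep(Us_idx[p, s], length(nzr))); tv <- c(tv, val[nzr])
        }
      }
      if (nslack > 0) {
        for (p in seq_len(npc_pts)) {
          rows <- (p - 1L) * np + ineq_rows
          ti <- c(ti, rows); tj <- c(tj, islack[p, ])
          tv <- c(tv, -1 / ocp$path_scale[ineq_rows])
        }
      }
      Jp <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(npc_pts * np, nz))
      blocks <- c(blocks, list(Jp))
    }
    if (length(blocks) == 0) return(NULL)
    do.call(rbind, blocks)
  }

  # ---- objective ----------------------------------------------------------
  terms <- if (is.function(ocp$objective)) ocp$objective(layout) else ocp$objective
  quad_terms <- Filter(function(t) !is.null(t$A), terms)
  mayer_tf <- sum(vapply(terms, function(t) if (!is.null(t$mayer_tf)) t$mayer_tf else 0,
                         numeric(1)))
  qt_pre <- lapply(quad_terms, function(t) {
    A <- t$A
    if (ncol(A) < nz) {
      A <- cbind(A, Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                         dims = c(nrow(A), nz - ncol(A))))
    }
    As <- A %*% Svar
    bs <- t$b - as.numeric(A %*% mid)
    AtW <- Matrix::t(As) %*% Matrix::Diagonal(length(t$W), t$W)
    list(name = t$name, As = As, bs = bs, W = t$W, AtW = AtW,
         AtWA = AtW %*% As)
  })
  H_base <- if (length(qt_pre) > 0) {
    Reduce(`+`, lapply(qt_pre, function(q) 2 * q$AtWA))
  } else Matrix::Diagonal(nz, 0)

  obj_s <- function(zs) {
    tf_cur <- if (layout$free_tf) mid[layout$itf] + s_eff[layout$itf] * zs[layout$itf] else tf_guess
    f <- mayer_tf * tf_cur
    g <- numeric(nz)
    qsum_vec <- numeric(nz) # gradient of sum of quadratic forms wrt zs
    qtot <- 0
    for (q in qt_pre) {
      r <- q$bs - as.numeric(q$As %*% zs)
      qv <- sum(q$W * r * r)
      qtot <- qtot + qv
      qsum_vec <- qsum_vec - 2 * as.numeric(q$AtW %*% r)
    }
    f <- f + tf_cur * qtot
    g <- tf_cur * qsum_vec
    H <- tf_cur * H_base
    if (layout$free_tf) {
      stf <- s_eff[layout$itf]
      g[layout$itf] <- g[layout$itf] + stf * (qtot + mayer_tf)
      # cross second derivatives between tf and the quadratic residuals, plus
      # a unit proximal curvature on the horizon variable itself (its direct
      # objective curvature is zero, which would otherwise leave the Newton
      # model unbounded in that direction)
      cross <- stf * qsum_vec
      H <- H + Matrix::sparseMatrix(
        i = c(rep(layout$itf, nz), seq_len(nz), layout$itf),
        j = c(seq_len(nz), rep(layout$itf, nz), layout$itf),
        x = c(cross, cross, 1), dims = c(nz, nz))
    }
    list(f = f, g = g, H = H)
  }

  con_s <- function(zs) {
    z <- unscale(zs)
    c(as.numeric(A_lin_s %*% zs) - b_lin_s, con_nl(z))
  }
  # constraint curvature: under a free horizon the dynamics rows are bilinear
  # in (tf, states/controls); their exact cross-Hessian is the (A, B)-part of
  # the dynamics Jacobian divided by tf, contracted with the multipliers
  hess_con_s <- NULL
  if (layout$free_tf && dyn_nonconst) {
    n_lin_rows <- nrow(A_lin)
    n_dyn_rows <- N * d * nx
    hess_con_s <- function(zs, lam) {
      z <- unscale(zs)
      tf_cur <- z[layout$itf]
      Jfull <- jac_nl(z)
      Jdyn <- Jfull[seq_len(n_dyn_rows), , drop = FALSE]
      M_ab <- Jdyn - A_D
      M_ab[, layout$itf] <- 0
      lam_dyn <- lam[n_lin_rows + seq_len(n_dyn_rows)]
      cross <- as.numeric(Matrix::crossprod(M_ab, lam_dyn)) / tf_cur
      # scale into the solver's variable space and symmetrize
      cross <- cross * s_eff
      idx <- which(cross != 0)
      Matrix::sparseMatrix(
        i = c(idx, rep(layout$itf, length(idx))),
        j = c(rep(layout$itf, length(idx)), idx),
        x = c(cross[idx], cross[idx]) * s_eff[layout$itf] / s_eff[layout$itf],
        dims = c(nz, nz)) * s_eff[layout$itf]
    }
  }
  jac_s <- function(zs) {
    z <- unscale(zs)
    Jnl <- jac_nl(z)
    if (is.null(Jnl)) return(A_lin_s)
    rbind(A_lin_s, Jnl %*% Svar)
  }

  structure(list(ocp = ocp, layout = layout, nz = nz,
                 lb_s = lb_s, ub_s = ub_s, z0_s = z0_s,
                 mid = mid, s_eff = s_eff, unscale = unscale,
                 obj = obj_s, con = con_s, jac = jac_s, hess_con = hess_con_s,
                 qt_pre = qt_pre, mayer_tf = mayer_tf,
                 tf_guess = tf_guess, nslack = nslack, islack = islack,
                 has_con = TRUE), class = "ocp_nlp")
}

#' Solve a transcribed optimal control problem
#'
#' Runs the interior-point solver on the scaled NLP and unscales the result
#' into state/control trajectories.
#'
#' @param ocp an `ocp_def` or a transcribed `ocp_nlp`.
#' @param control solver options passed to [solve_ipnlp()].
#' @return an `ocp_solution`: list with `X` (N x (d+1) x nx state array),
#'   `U` (control-node matrix), `tf`, `times` (matrix matching `X`'s first
#'   two dimensions), `objective`, `breakdown`, `status`, `iterations`,
#'   `kkt_error`.
#' @export
solve_ocp <- function(ocp, control = list()) {
  nlp <- if (inherits(ocp, "ocp_nlp")) ocp else transcribe(ocp)
  res <- solve_ipnlp(nlp$z0_s, nlp$lb_s, nlp$ub_s, nlp$obj,
                     con = nlp$con, jac = nlp$jac, hess_con = nlp$hess_con,
                     control = control)
  z <- nlp$unscale(res$x)
  lay <- nlp$layout
  tf <- if (lay$free_tf) z[lay$itf] else nlp$tf_guess
  X <- array(z[lay$ix], dim = dim(lay$ix))
  U <- matrix(z[lay$iu], nrow = nrow(lay$iu))
  times <- lay$tau_grid * tf
  zs <- res$x
  breakdown <- vapply(nlp$qt_pre, function(q) {
    r <- q$bs - as.numeric(q$As %*% zs)
    tf * sum(q$W * r * r)
  }, numeric(1))
  names(breakdown) <- vapply(nlp$qt_pre, `[[`, character(1), "name")
  if (nlp$mayer_tf != 0) breakdown <- c(breakdown, time = nlp$mayer_tf * tf)
  structure(list(X = X, U = U, tf = tf, times = times, z = z,
                 objective = res$f, breakdown = breakdown,
                 status = res$status, iterations = res$iterations,
                 kkt_error = res$kkt_error, layout = lay, nlp = nlp),
            class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat("<ocp_solution> status:", x$status, " objective:", format(x$objective),
      " tf:", format(x$tf), " iterations:", x$iterations, "\n")
  invisible(x)
}

#' State trajectory of a solution on its collocation grid
#'
#' @param sol an `ocp_solution`.
#' @param dedup drop duplicated interval-start points (default TRUE).
#' @return list with `t` (times) and `X` (matrix, one column per state).
#' @export
solution_grid <- function(sol, dedup = TRUE) {
  lay <- sol$layout
  N <- lay$N; d <- lay$d
  tt <- as.vector(t(sol$times))
  Xm <- matrix(NA_real_, N * (d + 1), lay$nx)
  r <- 0L
  for (i in seq_len(N)) for (k in 0:d) {
    r <- r + 1L
    Xm[r, ] <- sol$X[i, k + 1, ]
  }
  if (dedup) {
    keep <- rep(TRUE, N * (d + 1))
    if (N > 1) keep[(seq_len(N - 1)) * (d + 1) + 1] <- FALSE
    tt <- tt[keep]; Xm <- Xm[keep, , drop = FALSE]
  }
  list(t = tt, X = Xm)
}
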