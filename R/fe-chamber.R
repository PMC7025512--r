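# Chamber finite-element solver: Taylor-Hood (P2 displacement / P1 pressure)
# tetrahedra, incompressible Guccione myocardium with active fiber stress,
# cavity volumes prescribed through scalar Lagrange multipliers (the cavity
# pressures), zero-mean translation/rotation multipliers and an in-plane
# basal constraint.  Element kernels live in compiled code; assembly of the
# bordered KKT system and the Newton loop live here.

#' Cavity volume from an endocardial surface
#'
#' Divergence-theorem volume of a closed (or basal-plane-closed) cavity
#' surface.  The basal closure lies in the z = 0 plane where `x . n = 0`, so
#' it contributes nothing and is omitted.
#'
#' @param mesh A `bv_mesh`.
#' @param u Optional vertex displacement (N x 3 matrix or 3N vector).
#' @param chamber Cavity name (`"LV"` or `"RV"`).
#' @return Volume in ml; errors if the oriented volume is negative.
#' @export
cavity_volume <- function(mesh, u = NULL, chamber = "LV") {
  tri <- mesh$cavities[[chamber]]
  if (is.null(tri)) stop("unknown chamber: ", chamber, call. = FALSE)
  x <- mesh$nodes
  if (!is.null(u)) x <- x + .as_disp_matrix(u)[seq_len(nrow(x)), , drop = FALSE]
  v <- sum(.det3_rows(x, tri)) / 6 / 1000
  if (v <= 0)
    stop(sprintf("negative oriented cavity volume for surface '%s'", chamber),
         call. = FALSE)
  v
}

# ---- P2 scaffolding ------------------------------------------------------

.build_p2 <- function(mesh) {
  tets <- mesh$tets; nodes <- mesh$nodes
  ev <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
              tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(ev[, 1], ev[, 2]); hi <- pmax(ev[, 1], ev[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  emap <- match(key, key[first])
  Nv <- nrow(nodes)
  enodes <- (nodes[lo[first], , drop = FALSE] +
               nodes[hi[first], , drop = FALSE]) / 2
  coords <- rbind(nodes, enodes)
  M <- nrow(tets)
  tets10 <- cbind(tets, matrix(Nv + emap, M, 6))
  edge_lookup <- stats::setNames(Nv + seq_len(sum(first)), key[first])
  list(coords = coords, tets10 = tets10, Nv = Nv, N2 = nrow(coords),
       edge_lookup = edge_lookup)
}

.edge_id <- function(lookup, a, b) {
  unname(lookup[paste(pmin(a, b), pmax(a, b))])
}

# subdivide vertex facets into 4 subtriangles through the P2 edge nodes
.cavity_subtris <- function(tri, lookup) {
  e12 <- .edge_id(lookup, tri[, 1], tri[, 2])
  e23 <- .edge_id(lookup, tri[, 2], tri[, 3])
  e31 <- .edge_id(lookup, tri[, 3], tri[, 1])
  rbind(cbind(tri[, 1], e12, e31),
        cbind(e12, tri[, 2], e23),
        cbind(e31, e23, tri[, 3]),
        cbind(e12, e23, e31))
}

# volume (mm^3), gradient and Hessian triplets of (1/6) sum det(x1,x2,x3)
.cav_volume <- function(x, sub) sum(.det3_rows(x, sub)) / 6

.cav_grad <- function(x, sub, N2) {
  g <- matrix(0, N2, 3)
  x1 <- x[sub[, 1], , drop = FALSE]
  x2 <- x[sub[, 2], , drop = FALSE]
  x3 <- x[sub[, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  add <- function(idx, val) {
    for (d in 1:3) {
      s <- rowsum(val[, d], idx)
      g[as.integer(rownames(s)), d] <<- g[as.integer(rownames(s)), d] + s[, 1]
    }
  }
  add(sub[, 1], cr(x2, x3) / 6)
  add(sub[, 2], cr(x3, x1) / 6)
  add(sub[, 3], cr(x1, x2) / 6)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
                            3, 3)

# Hessian triplets (on u dofs, 1-based 3*(n-1)+d indexing): per subtriangle
# the blocks (1,2) = -skew(x3)/6, (1,3) = +skew(x2)/6, (2,3) = -skew(x1)/6
# and their transposes.
.cav_hess_triplets <- function(x, sub) {
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  x1 <- x[sub[, 1], , drop = FALSE]
  x2 <- x[sub[, 2], , drop = FALSE]
  x3 <- x[sub[, 3], , drop = FALSE]
  blk <- function(na, nb, vmat, sgn) {
    # skew(v) = [[0,-v3,v2],[v3,0,-v1],[-v2,v1,0]]
    for (r in 1:3) for (c in 1:3) {
      if (r == c) next
      val <- switch(paste(r, c),
                    "1 2" = -vmat[, 3], "1 3" = vmat[, 2],
                    "2 1" = vmat[, 3], "2 3" = -vmat[, 1],
                    "3 1" = -vmat[, 2], "3 2" = vmat[, 1])
      ii <<- c(ii, 3 * (na - 1) + r)
      jj <<- c(jj, 3 * (nb - 1) + c)
      vv <<- c(vv, sgn * val / 6)
    }
  }
  blk(sub[, 1], sub[, 2], x3, -1); blk(sub[, 2], sub[, 1], x3, +1)
  blk(sub[, 1], sub[, 3], x2, +1); blk(sub[, 3], sub[, 1], x2, -1)
  blk(sub[, 2], sub[, 3], x1, -1); blk(sub[, 3], sub[, 2], x1, +1)
  list(i = ii, j = jj, x = vv)
}

# ---- sparse KKT factorization --------------------------------------------
# The bordered saddle system is factored with a supernodal LDL' after
# symmetrizing (the finite-difference/active-stress asymmetry is tiny) and
# adding a quasi-definite regularization: +delta on the primal block,
# -delta on multiplier blocks.  This keeps the factorization stable without
# pivoting and is an order of magnitude faster than sparse LU at these
# sizes; the Newton residual is always evaluated on the unregularized
# system, so the regularization only perturbs the step, not the solution.
# Falls back to sparse LU if CHOLMOD refuses the matrix.
.kkt_factor <- function(A, n_primal, delta_rel = 1e-8) {
  n <- nrow(A)
  As <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  d <- Matrix::diag(A)[seq_len(n_primal)]
  sc <- mean(abs(d[d != 0]))
  if (!is.finite(sc) || sc == 0) sc <- 1
  reg <- c(rep(delta_rel * sc, n_primal), rep(-delta_rel * sc, n - n_primal))
  Aq <- As + Matrix::Diagonal(n, reg)
  ch <- tryCatch(Matrix::Cholesky(Aq, LDL = TRUE, super = FALSE,
                                  perm = TRUE),
                 error = function(e) NULL)
  if (!is.null(ch)) {
    f <- list(kind = "ldl", f = ch, A = A)
    # sanity check the (refined) factorization quality on a probe vector
    b <- rep(1, n)
    x <- tryCatch(.kkt_solve(f, b), error = function(e) NULL)
    if (!is.null(x)) {
      rr <- max(abs(as.numeric(A %*% x) - b)) / max(1, max(abs(x)) * sc)
      if (is.finite(rr) && rr < 1e-8) return(f)
    }
  }
  list(kind = "lu", f = Matrix::lu(A))
}

# LDL' of the regularized matrix + iterative refinement against the true
# matrix recovers full accuracy despite the regularization shift.
.kkt_solve <- function(fact, b) {
  x <- as.numeric(Matrix::solve(fact$f, b))
  if (fact$kind == "ldl") {
    for (k in 1:3) {
      r <- b - as.numeric(fact$A %*% x)
      if (max(abs(r)) < 1e-12 * max(1, max(abs(b)))) break
      x <- x + as.numeric(Matrix::solve(fact$f, r))
    }
  }
  x
}

# ---- chamber model -------------------------------------------------------

#' Build a chamber finite-element model
#'
#' Prepares the quadratic/linear discretization, cavity facet subdivisions,
#' constraint weights and material tables for [solve_chamber_pressures()].
#'
#' @param mesh A `bv_mesh`.
#' @param materials Named list per material group with entries
#'   `passive` ([guccione_params()]) and `active` ([active_params()]).
#'   Groups: `LV` (applied to LVFW + septum) and `RV` (RVFW); a single
#'   group `LV` suffices for single-region meshes.
#' @return An object of class `chamber_model`.
#' @export
fe_chamber <- function(mesh, materials = list(
  LV = list(passive = guccione_params(C = 280),
            active = active_params(T_0 = 2000e3, iso_variant = "ascending")),
  RV = list(passive = guccione_params(C = 170),
            active = active_params(T_0 = 1800e3, iso_variant = "ascending")))) {
  p2 <- .build_p2(mesh)
  matid <- ifelse(mesh$region == "RVFW", 1L, 0L)
  if (is.null(materials$RV)) matid[] <- 0L
  gl <- materials$LV; gr <- if (is.null(materials$RV)) materials$LV else materials$RV
  gucc <- rbind(unlist(gl$passive[c("C", "b_ff", "b_xx", "b_fx")]),
                unlist(gr$passive[c("C", "b_ff", "b_xx", "b_fx")]))
  actrow <- function(a) c(a$T_0, a$t_r, a$t_d, a$b, a$l_d, a$a_6, a$a_7,
                          a$E_a, a$v_0, a$l_s0,
                          ifelse(a$iso_variant == "printed", 0, 1))
  act <- rbind(actrow(gl$active), actrow(gr$active))
  fib <- cbind(mesh$fibers$f, mesh$fibers$s, mesh$fibers$n)
  cavsub <- lapply(mesh$cavities, .cavity_subtris, lookup = p2$edge_lookup)
  w <- bv_weights_cpp(p2$coords, p2$tets10)
  base_p2 <- which(abs(p2$coords[, 3]) < 1e-8)
  if (length(mesh$base_nodes) == 0) base_p2 <- integer(0)
  fixed_u <- 3 * (base_p2 - 1) + 3          # basal z dofs
  free_u <- setdiff(seq_len(3 * p2$N2), fixed_u)
  freemask <- logical(3 * p2$N2); freemask[free_u] <- TRUE
  cav_border_dofs <- lapply(cavsub, function(sub) {
    nodes <- sort(unique(as.vector(sub)))
    dofs <- rep(3 * (nodes - 1), each = 3) + rep(1:3, length(nodes))
    dofs[freemask[dofs]]
  })
  structure(list(mesh = mesh, coords = p2$coords, tets10 = p2$tets10,
                 Nv = p2$Nv, N2 = p2$N2, matid = matid, gucc = gucc,
                 act = act, fib = fib, cavsub = cavsub,
                 w0 = w$w0, w1 = w$w1, free_u = free_u,
                 cav_border_dofs = cav_border_dofs,
                 materials = materials,
                 lc0 = act[1, 10] - 1 / act[1, 8]),
            class = "chamber_model")
}

.chamber_state0 <- function(model) {
  M <- nrow(model$tets10)
  ncav <- length(model$cavsub)
  lc0 <- matrix(0, M, 4)
  for (e in seq_len(M)) {
    a <- model$act[model$matid[e] + 1, ]
    lc0[e, ] <- a[10] - 1 / a[8]
  }
  list(u = numeric(3 * model$N2), p = numeric(model$Nv),
       P = stats::setNames(numeric(ncav), names(model$cavsub)),
       c1 = numeric(3), c2 = numeric(3), lc = lc0, t_act = -1)
}

.chamber_volumes <- function(model, u) {
  x <- model$coords + matrix(u, ncol = 3, byrow = TRUE)
  vapply(model$cavsub, function(s) .cav_volume(x, s) / 1000, numeric(1))
}

#' Solve the chamber model at prescribed cavity volumes
#'
#' Newton's method on the full mixed system (displacement, incompressibility
#' pressure, cavity-pressure multipliers, rigid-body multipliers), with
#' automatic volume sub-stepping.  The converged cavity-pressure Lagrange
#' multipliers are the chamber pressures.
#'
#' @param model A `chamber_model` (or a `bv_mesh`, from which a model with
#'   default materials is built).
#' @param volumes Named target cavity volumes in ml (names matching the
#'   mesh cavities, e.g. `c(LV = 80, RV = 90)`).
#' @param t_act Time since ventricular activation (ms); negative disables
#'   active stress.
#' @param state Warm-start state from a previous solve (or NULL).
#' @param control List: `rtol` (1e-8), `atol` (1e-10), `maxit` (25),
#'   `substep_ml` (2), `vol_tol_ml` (1e-3), `cache` (environment for
#'   tangent reuse across calls), `lagged_iters` (number of quasi-Newton
#'   iterations on the cached tangent before a refresh, default 3).
#' @return A `chamber_solve_result` with cavity pressures `P` (Pa),
#'   displacement, convergence diagnostics and sarcomere lengths.
#' @export
solve_chamber_pressures <- function(model, volumes, t_act = -1,
                                    state = NULL, control = list()) {
  if (inherits(model, "bv_mesh")) model <- fe_chamber(model)
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, floor = 1e-3,
                                maxit = 25, substep_ml = 2,
                                vol_tol_ml = 1e-3,
                                cache = NULL, lagged_iters = 3,
                                max_substep_fail = 3), control)
  if (is.null(state)) state <- .chamber_state0(model)
  state <- state[intersect(.state_fields, names(state))]
  state$t_act <- t_act
  cav_names <- names(model$cavsub)
  volumes <- volumes[cav_names]
  if (anyNA(volumes) || any(volumes <= 0))
    stop("target volumes must be positive for cavities: ",
         paste(cav_names, collapse = ", "), call. = FALSE)

  v_cur <- .chamber_volumes(model, state$u)
  dmax <- max(abs(volumes - v_cur))
  nsub <- max(1L, ceiling(dmax / ctl$substep_ml))
  if (isTRUE(ctl$verbose))
    message(sprintf("solve: v_cur %s -> target %s, nsub %d, substep %.3g",
                    paste(signif(v_cur, 6), collapse = "/"),
                    paste(signif(volumes, 6), collapse = "/"), nsub,
                    ctl$substep_ml))
  iters_total <- 0L
  for (k in seq_len(nsub)) {
    tgt <- v_cur + (volumes - v_cur) * k / nsub
    st <- .chamber_newton(model, tgt, state, ctl)
    if (!st$converged && ctl$substep_ml > 4 * ctl$vol_tol_ml) {
      # recursive refinement of this sub-interval
      ctl2 <- ctl; ctl2$substep_ml <- ctl$substep_ml / 4
      st <- solve_chamber_pressures(model, tgt, t_act = t_act,
                                    state = state, control = ctl2)
      st <- st$state
    }
    if (!st$converged)
      stop("chamber Newton failed to converge; residual history: ",
           paste(signif(st$hist, 3), collapse = ", "),
           " (try smaller volume increments)", call. = FALSE)
    state <- st
    iters_total <- iters_total + st$iters
  }

  res <- bv_residual_cpp(model$coords, model$tets10, state$u, state$p,
                         model$matid, model$gucc, model$act, model$fib,
                         state$lc, state$t_act)
  vols <- .chamber_volumes(model, state$u)
  structure(list(P = state$P, u = state$u, p = state$p, c1 = state$c1,
                 c2 = state$c2, converged = TRUE,
                 newton_iters = iters_total, volumes = vols,
                 energy = res$energy,
                 avg_absJm1 = res$int_absJm1 / 1.0789333 / sum(.tet_vol6(
                   model$mesh$nodes, model$mesh$tets) / 6),
                 ls = res$ls, state = state),
            class = "chamber_solve_result")
}

# one Newton solve at fixed targets; returns updated state
.state_fields <- c("u", "p", "P", "c1", "c2", "lc", "t_act")

.chamber_newton <- function(model, tgt_ml, state, ctl) {
  state <- state[.state_fields]
  N2 <- model$N2; Nv <- model$Nv
  free_u <- model$free_u
  ncav <- length(model$cavsub)
  ndof <- length(free_u) + Nv + ncav + 6
  u_ids <- seq_along(free_u)                      # reduced ids
  p_ids <- length(free_u) + seq_len(Nv)
  P_ids <- length(free_u) + Nv + seq_len(ncav)
  c_ids <- length(free_u) + Nv + ncav + 1:6
  red <- integer(3 * N2); red[free_u] <- u_ids    # full u dof -> reduced

  tgt_mm3 <- tgt_ml * 1000
  x <- state
  hist <- numeric(0)
  res0 <- NA_real_
  fact <- NULL; fact_age <- Inf
  cache <- ctl$cache
  if (!is.null(cache) && !is.null(cache$fact) &&
      identical(cache$ndof, ndof)) {
    fact <- cache$fact; fact_age <- 0
  }

  resid <- function(s) {
    rr <- bv_residual_cpp(model$coords, model$tets10, s$u, s$p, model$matid,
                          model$gucc, model$act, model$fib, s$lc, s$t_act)
    if (!rr$ok) return(NULL)
    xdef <- model$coords + matrix(s$u, ncol = 3, byrow = TRUE)
    gV <- lapply(model$cavsub, function(sub) cav_grad_cpp(xdef, sub))
    V <- vapply(model$cavsub, function(sub) .cav_volume(xdef, sub), numeric(1))
    ru <- rr$res_u
    for (k in seq_len(ncav)) ru <- ru - s$P[k] * as.vector(t(gV[[k]]))
    umat <- matrix(s$u, ncol = 3, byrow = TRUE)
    # rigid-body constraint values and their adjoint on u
    C1u <- colSums(model$w0 * umat)
    C2u <- colSums(cbind(
      model$w1[, 2] * umat[, 3] - model$w1[, 3] * umat[, 2],
      model$w1[, 3] * umat[, 1] - model$w1[, 1] * umat[, 3],
      model$w1[, 1] * umat[, 2] - model$w1[, 2] * umat[, 1]))
    adj <- -(model$w0 %o% s$c1) -
      cbind(model$w1[, 3] * s$c2[2] - model$w1[, 2] * s$c2[3],
            model$w1[, 1] * s$c2[3] - model$w1[, 3] * s$c2[1],
            model$w1[, 2] * s$c2[1] - model$w1[, 1] * s$c2[2])
    ru <- ru + as.vector(t(adj))
    list(R = c(ru[free_u], rr$res_p, -(V - tgt_mm3), -C1u, -C2u),
         gV = gV, V = V)
  }

  rs <- resid(x)
  if (is.null(rs)) return(c(x, list(converged = FALSE, iters = 0L,
                                    hist = NA_real_)))
  if (isTRUE(ctl$verbose))
    message(sprintf("newton entry: rn0 %.3g tgt %s", max(abs(rs$R)),
                    paste(signif(tgt_ml, 6), collapse = "/")))
  nrm <- function(R) { v <- max(abs(R)); if (is.finite(v)) v else Inf }
  rn <- nrm(rs$R)
  res0 <- max(rn, 1e-8)
  iters <- 0L
  rn_ref <- rn
  repeat {
    vol_ok <- all(abs(rs$V - tgt_mm3) < ctl$vol_tol_ml * 1000)
    if ((rn < ctl$floor ||
         ((rn < ctl$rtol * res0 || rn < ctl$atol * (1 + res0)) &&
          rn < 1000 * (1 + ctl$floor))) && vol_ok) {
      if (isTRUE(ctl$verbose))
        message(sprintf("exit converged: rn %.3g res0 %.3g iters %d", rn,
                        res0, iters))
      return(c(x, list(converged = TRUE, iters = iters, hist = hist)))
    }
    if (iters >= ctl$maxit) {
      if (isTRUE(ctl$verbose)) message("exit maxit")
      return(c(x, list(converged = FALSE, iters = iters, hist = hist)))
    }

    if (is.null(fact) || fact_age >= ctl$lagged_iters) {
      tg <- bv_tangent_cpp(model$coords, model$tets10, x$u, x$p, model$matid,
                           model$gucc, model$act, model$fib, x$lc, x$t_act)
      if (!tg$ok) return(c(x, list(converged = FALSE, iters = iters,
                                   hist = hist)))
      xdef <- model$coords + matrix(x$u, ncol = 3, byrow = TRUE)
      # collect triplet blocks, then concatenate once
      ti <- list(); tj <- list(); tv <- list()
      push <- function(i, j, v) {
        k <- length(ti) + 1L
        ti[[k]] <<- i; tj[[k]] <<- j; tv[[k]] <<- v
      }
      # element block (u, p): map K indices (first 3*N2 u dofs, then Nv p)
      # all index sets below are state-independent, so the assembled
      # sparsity pattern is identical at every refresh and can be cached
      mapid <- c(red, length(free_u) + seq_len(Nv))
      keep <- mapid[tg$i] > 0 & mapid[tg$j] > 0
      push(mapid[tg$i][keep], mapid[tg$j][keep], tg$x[keep])
      # cavity Hessians: - sum_k P_k HessV_k (kept in the pattern even at
      # P = 0 so the pattern is refresh-invariant)
      for (k in seq_len(ncav)) {
        ht <- .cav_hess_triplets(xdef, model$cavsub[[k]])
        hk <- red[ht$i] > 0 & red[ht$j] > 0
        push(red[ht$i][hk], red[ht$j][hk], -x$P[k] * ht$x[hk])
      }
      # borders: cavity volume gradients over the (fixed) cavity node dofs
      for (k in seq_len(ncav)) {
        gvk <- as.vector(t(rs$gV[[k]]))
        nz <- model$cav_border_dofs[[k]]
        push(red[nz], rep(P_ids[k], length(nz)), -gvk[nz])
        push(rep(P_ids[k], length(nz)), red[nz], -gvk[nz])
      }
      # rigid-body borders over all free u dofs
      w0r <- model$w0
      nzr <- which(red[seq_len(3 * N2)] > 0)
      for (d in 1:3) {
        colv <- numeric(3 * N2); colv[3 * (seq_len(N2) - 1) + d] <- w0r
        push(red[nzr], rep(c_ids[d], length(nzr)), -colv[nzr])
        push(rep(c_ids[d], length(nzr)), red[nzr], -colv[nzr])
      }
      # rotation rows: (m1 x u)_d
      w1 <- model$w1
      rot_cols <- list(
        cbind(0, -w1[, 3], w1[, 2]),
        cbind(w1[, 3], 0, -w1[, 1]),
        cbind(-w1[, 2], w1[, 1], 0))
      for (d in 1:3) {
        colv <- as.vector(t(rot_cols[[d]]))
        push(red[nzr], rep(c_ids[3 + d], length(nzr)), -colv[nzr])
        push(rep(c_ids[3 + d], length(nzr)), red[nzr], -colv[nzr])
      }
      ii2 <- unlist(ti); jj2 <- unlist(tj); vv2 <- unlist(tv)
      n_primal <- length(free_u) + Nv
      sc <- if (!is.null(cache) && !is.null(cache$diag_scale))
        cache$diag_scale
      else {
        du <- abs(vv2[ii2 == jj2 & ii2 <= n_primal])
        max(mean(du[du != 0]), 1e-8)
      }
      if (!is.null(cache)) cache$diag_scale <- sc
      # tiny quasi-definite diagonal keeps the factorization stable;
      # symmetrization happens at triplet level (the mild active-stress
      # nonsymmetry only perturbs the Newton direction, never the residual)
      reg <- c(rep(1e-9 * sc, n_primal), rep(-1e-9 * sc, ndof - n_primal))
      vals <- c(vv2 / 2, vv2 / 2, reg)
      ia <- c(ii2, jj2, seq_len(ndof)); ja <- c(jj2, ii2, seq_len(ndof))
      tk <- pmin(ia, ja) + (pmax(ia, ja) - 1) * as.numeric(ndof)
      Aq <- NULL
      if (!is.null(cache) && !is.null(cache$slotkey) &&
          identical(cache$ndof, ndof)) {
        # refill the cached pattern by slot key; a key outside the cached
        # pattern (the finite-difference zero pattern can shift) forces a
        # rebuild below
        sm <- match(tk, cache$slotkey)
        if (!anyNA(sm)) {
          # both symmetric halves of the stream fold onto the same upper
          # slot, so off-diagonal sums carry a factor 2 relative to the
          # stored upper-triangle values
          xs <- numeric(length(cache$slotkey))
          agg <- rowsum(vals, sm)
          xs[as.integer(rownames(agg))] <- agg
          xs[cache$offdiag] <- xs[cache$offdiag] / 2
          Aq <- cache$Aq_tmpl
          Aq@x <- xs
        }
      }
      if (is.null(Aq)) {
        Aq <- Matrix::forceSymmetric(Matrix::sparseMatrix(
          i = ia, j = ja, x = vals, dims = c(ndof, ndof)))
        if (!is.null(cache)) {
          rows <- Aq@i + 1
          cols <- rep.int(seq_len(ndof), diff(Aq@p))
          cache$slotkey <- rows + (cols - 1) * as.numeric(ndof)
          cache$offdiag <- rows != cols
          cache$Aq_tmpl <- Aq
        }
      }
      fact <- tryCatch({
        ch <- if (!is.null(cache) && !is.null(cache$chS) &&
                  identical(cache$ndof, ndof))
          Matrix::update(cache$chS, Aq)
        else Matrix::Cholesky(Aq, LDL = TRUE, super = FALSE, perm = TRUE)
        list(kind = "ldl", f = ch, A = Aq)
      }, error = function(e) NULL)
      if (!is.null(fact) && !is.null(cache)) cache$chS <- fact$f
      if (is.null(fact)) fact <- list(kind = "lu", f = Matrix::lu(Aq))
      fact_age <- 0
      rn_ref <- rn
      if (!is.null(cache)) { cache$fact <- fact; cache$ndof <- ndof }
    }

    dx <- tryCatch(.kkt_solve(fact, -rs$R), error = function(e) NULL)
    if (is.null(dx)) {
      if (fact_age == 0) return(c(x, list(converged = FALSE, iters = iters,
                                          hist = hist)))
      fact <- NULL; next
    }
    # line search on the affine-invariant merit |J^{-1} R| (one extra
    # backsolve per trial): the raw residual mixes force and volume units
    # and misjudges progress when a step trades one for the other.  A step
    # that does not improve the merit is never accepted.
    m_old <- max(abs(dx))
    trial <- function(alpha) {
      xn <- x
      du <- numeric(3 * N2); du[free_u] <- dx[u_ids]
      xn$u <- x$u + alpha * du
      xn$p <- x$p + alpha * dx[p_ids]
      xn$P <- x$P + alpha * dx[P_ids]
      xn$c1 <- x$c1 + alpha * dx[c_ids[1:3]]
      xn$c2 <- x$c2 + alpha * dx[c_ids[4:6]]
      rsn <- resid(xn)
      if (is.null(rsn) || !is.finite(nrm(rsn$R)))
        return(list(m = Inf, xn = xn, rsn = NULL))
      mn <- tryCatch(max(abs(.kkt_solve(fact, rsn$R))),
                     error = function(e) Inf)
      list(m = mn, xn = xn, rsn = rsn)
    }
    alpha <- 1; best <- NULL; m_new <- Inf
    repeat {
      tr <- trial(alpha)
      if (is.finite(tr$m) && tr$m < (1 - 0.25 * alpha) * m_old) {
        best <- tr; m_new <- tr$m; break
      }
      if (is.finite(tr$m) && (is.null(best) || tr$m < best$m)) best <- tr
      alpha <- alpha / 2
      if (alpha < 1 / 128) break
    }
    if (!is.null(best) && is.finite(best$m) && best$m < m_old) {
      m_new <- best$m; rsn <- best$rsn; xn <- best$xn
    } else {
      # no improving step along this direction
      if (fact_age > 0) { fact <- NULL; next }
      if (isTRUE(ctl$verbose)) message("exit: no improving step")
      return(c(x, list(converged = FALSE, iters = iters, hist = hist)))
    }
    if (isTRUE(ctl$verbose))
      message(sprintf(
        "it %d: rn %.3g -> %.3g merit %.3g -> %.3g alpha %.3g age %d volerr %.2g",
        iters, rn, nrm(rsn$R), m_old, m_new, alpha, fact_age,
        max(abs(rsn$V - tgt_mm3))))
    # a stale tangent that only crawls is worth rebuilding
    slow <- fact_age >= 5 && m_new > 0.7 * m_old
    x <- xn; rs <- rsn; rn <- nrm(rs$R)
    hist <- c(hist, rn)
    iters <- iters + 1L
    fact_age <- fact_age + 1
    if (slow) fact <- NULL
  }
}

#' Fiber stress field and region averages
#'
#' Cauchy fiber stress `sigma_f = (sigma e_f) . e_f` per cell, and
#' volume-weighted averages for the LV (free wall + septum) and RV regions.
#'
#' @param result A `chamber_solve_result`.
#' @param model The `chamber_model` that produced it.
#' @return List with a per-cell tibble `cells` and a named vector
#'   `averages` (Pa).
#' @export
fiber_stress_field <- function(result, model) {
  st <- result$state
  s <- bv_stress_cpp(model$coords, model$tets10, st$u, st$p, model$matid,
                     model$gucc, model$act, model$fib, st$lc, st$t_act)
  reg <- model$mesh$region
  grp <- ifelse(reg == "RVFW", "RV", "LV")
  cells <- tibble::tibble(region = reg, group = grp,
                          fiber_stress = s$fiber_stress, vol = s$vol,
                          s11 = s$sigma[, 1], s22 = s$sigma[, 2],
                          s33 = s$sigma[, 3], s12 = s$sigma[, 4],
                          s13 = s$sigma[, 5], s23 = s$sigma[, 6])
  av <- vapply(split(cells, grp), function(d)
    sum(d$fiber_stress * d$vol) / sum(d$vol), numeric(1))
  list(cells = cells, averages = av)
}

#' @export
#' @method print chamber_solve_result
print.chamber_solve_result <- function(x, ...) {
  cat("Chamber FE solve:",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(%d Newton iterations)\n", x$newton_iters))
  for (k in names(x$P))
    cat(sprintf("  P_%s = %.1f Pa (%.2f mmHg) at V = %.2f ml\n", k, x$P[k],
                x$P[k] / 133.322, x$volumes[k]))
  cat(sprintf("  volume-averaged |J - 1| = %.2e\n", x$avg_absJm1))
  invisible(x)
}
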