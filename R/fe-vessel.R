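# Membrane artery finite-element solver: 3-node membrane triangles carrying
# the constrained-mixture wall energy, cavity volume prescribed through a
# scalar Lagrange multiplier (the lumen pressure), inlet/outlet rings
# constrained to move in their planes, rigid-body multipliers, and a small
# transverse-displacement penalty that regularizes bending-free modes.

#' Build a vessel membrane model
#'
#' @param mesh A `vessel_mesh`.
#' @param material A [vessel_wall_material()].
#' @param pen_rel Relative transverse-penalty stiffness (default 1e-6 of
#'   the membrane stiffness scale per unit node area); numerical
#'   regularization, not part of the physical model.
#' @return An object of class `vessel_model`.
#' @export
fe_vessel <- function(mesh, material, pen_rel = 1e-6) {
  M <- nrow(mesh$tris); N <- nrow(mesh$nodes)
  r1r2 <- matrix(0, M, 4); Ah <- numeric(M); Aref <- numeric(M)
  for (e in seq_len(M)) {
    tr <- mesh$tris[e, ]
    X <- mesh$nodes[tr, ]
    t1 <- mesh$frames$e_l[e, ]; t2 <- mesh$frames$e_c[e, ]
    D <- cbind(c(sum((X[2, ] - X[1, ]) * t1), sum((X[2, ] - X[1, ]) * t2)),
               c(sum((X[3, ] - X[1, ]) * t1), sum((X[3, ] - X[1, ]) * t2)))
    Dinv <- solve(D)
    r1r2[e, ] <- c(Dinv[1, ], Dinv[2, ])
    Aref[e] <- abs(det(D)) / 2
    Ah[e] <- Aref[e] * mesh$h
  }
  mm <- constituent_masses(material)
  mp <- c(mm$M_e * material$c_1, mm$M_c * material$c_2, material$c_3,
          mm$M_m * material$c_4, material$c_5)
  dirs <- family_directions(material$alpha)
  # node areas and reference normals for the transverse penalty
  A_node <- numeric(N); n_node <- matrix(0, N, 3)
  for (e in seq_len(M)) {
    tr <- mesh$tris[e, ]
    A_node[tr] <- A_node[tr] + Aref[e] / 3
    n_node[tr, ] <- n_node[tr, ] +
      matrix(mesh$frames$normal[e, ], 3, 3, byrow = TRUE) * Aref[e]
  }
  n_node <- n_node / pmax(sqrt(rowSums(n_node^2)), 1e-12)
  cscale <- mp[1] + sum(mp[2:5]) + mp[7]
  kappa <- pen_rel * mesh$h * cscale * A_node   # Pa*mm per node
  # ring constraint rows
  ring_nodes <- unlist(lapply(mesh$rings, function(r) r$nodes))
  ring_normals <- do.call(rbind, lapply(mesh$rings, function(r)
    matrix(r$normal / sqrt(sum(r$normal^2)), length(r$nodes), 3,
           byrow = TRUE)))
  # lumped rigid-body weights
  w0 <- A_node * mesh$h
  structure(list(mesh = mesh, material = material, r1r2 = r1r2, Ah = Ah,
                 Aref = Aref, mp = mp, dirs = dirs, kappa = kappa,
                 n_node = n_node, ring_nodes = ring_nodes,
                 ring_normals = ring_normals, w0 = w0, N = N, M = M),
            class = "vessel_model")
}

.vessel_state0 <- function(model) {
  list(u = numeric(3 * model$N), P = 0, c1 = numeric(3), c2 = numeric(3),
       lam = numeric(length(model$ring_nodes)))
}

#' Solve the vessel membrane at a prescribed cavity volume
#'
#' Newton's method on the bordered system; the converged volume-constraint
#' multiplier is the lumen pressure.
#'
#' @param model A `vessel_model` (or a `vessel_mesh`, combined with
#'   `material`).
#' @param V Target cavity volume, ml.
#' @param material Wall material (only used when `model` is a mesh).
#' @param state Warm-start state or NULL.
#' @param control List: `rtol` (1e-8), `atol` (1e-10), `maxit` (40),
#'   `substep_ml` (3), `vol_tol_ml` (1e-3).
#' @return A `vessel_solve_result` with pressure `P` (Pa), displacement,
#'   von Mises stress per element and diagnostics.
#' @export
solve_vessel_pressure <- function(model, V, material = NULL, state = NULL,
                                  control = list()) {
  if (inherits(model, "vessel_mesh")) {
    if (is.null(material)) stop("material required when passing a mesh",
                                call. = FALSE)
    model <- fe_vessel(model, material)
  }
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, floor = 1e-3,
                                maxit = 40, substep_ml = 3,
                                vol_tol_ml = 1e-3),
                           control)
  if (is.null(state)) state <- .vessel_state0(model)
  stopifnot(V > 0)
  v_cur <- vessel_cavity_volume(model$mesh, state$u)
  nsub <- max(1L, ceiling(abs(V - v_cur) / ctl$substep_ml))
  iters <- 0L
  for (k in seq_len(nsub)) {
    tgt <- v_cur + (V - v_cur) * k / nsub
    st <- .vessel_newton(model, tgt, state, ctl)
    if (!st$converged) {
      ctl2 <- ctl; ctl2$substep_ml <- ctl$substep_ml / 4
      sub <- solve_vessel_pressure(model, tgt, state = state, control = ctl2)
      st <- sub$state; st$converged <- TRUE; st$iters <- sub$newton_iters
    }
    state <- st
    iters <- iters + st$iters
  }
  vm <- memb_stress_cpp(model$mesh$nodes, model$mesh$tris, state$u,
                        model$r1r2, model$Ah, model$mp, model$dirs)
  structure(list(P = state$P, u = state$u, converged = TRUE,
                 newton_iters = iters,
                 volume = vessel_cavity_volume(model$mesh, state$u),
                 vm = vm$vm, s1 = vm$s1, s2 = vm$s2,
                 energy = memb_residual_cpp(model$mesh$nodes,
                                            model$mesh$tris, state$u,
                                            model$r1r2, model$Ah, model$mp,
                                            model$dirs)$energy,
                 state = state),
            class = "vessel_solve_result")
}

.vessel_newton <- function(model, tgt_ml, state, ctl) {
  N <- model$N
  mesh <- model$mesh
  nr <- length(model$ring_nodes)
  ndof <- 3 * N + 1 + 6 + nr
  P_id <- 3 * N + 1; c_ids <- 3 * N + 1 + 1:6; r_ids <- 3 * N + 7 + seq_len(nr)
  tgt_mm3 <- tgt_ml * 1000
  X <- mesh$nodes

  # cap fan triangles as pseudo-surface for the volume functional:
  # express caps as triangles (apex fixed) -> gradient contributions on ring
  cap_grad <- function(x) {
    g <- matrix(0, N, 3)
    V <- sum(.det3_rows(x, mesh$tris))
    for (r in mesh$rings) {
      idx <- r$nodes; nxt <- idx[c(2:length(idx), 1)]
      sgn <- if (isTRUE(r$flip_cap)) -1 else 1
      a <- r$apex
      b <- x[idx, , drop = FALSE]; c <- x[nxt, , drop = FALSE]
      V <- V + sgn * sum(a[1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
                           a[2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
                           a[3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
      # d det(a,b,c)/db = c x a ; /dc = a x b
      cxa <- cbind(c[, 2] * a[3] - c[, 3] * a[2],
                   c[, 3] * a[1] - c[, 1] * a[3],
                   c[, 1] * a[2] - c[, 2] * a[1])
      axb <- cbind(a[2] * b[, 3] - a[3] * b[, 2],
                   a[3] * b[, 1] - a[1] * b[, 3],
                   a[1] * b[, 2] - a[2] * b[, 1])
      for (d in 1:3) {
        s1 <- rowsum(sgn * cxa[, d], idx)
        g[as.integer(rownames(s1)), d] <- g[as.integer(rownames(s1)), d] + s1[, 1]
        s2 <- rowsum(sgn * axb[, d], nxt)
        g[as.integer(rownames(s2)), d] <- g[as.integer(rownames(s2)), d] + s2[, 1]
      }
    }
    # surface triangles
    x1 <- x[mesh$tris[, 1], , drop = FALSE]
    x2 <- x[mesh$tris[, 2], , drop = FALSE]
    x3 <- x[mesh$tris[, 3], , drop = FALSE]
    cr <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                               p[, 3] * q[, 1] - p[, 1] * q[, 3],
                               p[, 1] * q[, 2] - p[, 2] * q[, 1])
    add <- function(idx, val) {
      for (d in 1:3) {
        s <- rowsum(val[, d], idx)
        g[as.integer(rownames(s)), d] <<- g[as.integer(rownames(s)), d] + s[, 1]
      }
    }
    add(mesh$tris[, 1], cr(x2, x3))
    add(mesh$tris[, 2], cr(x3, x1))
    add(mesh$tris[, 3], cr(x1, x2))
    list(V = V / 6, g = g / 6)
  }

  resid <- function(s) {
    um <- matrix(s$u, ncol = 3, byrow = TRUE)
    x <- X + um
    rr <- memb_residual_cpp(X, mesh$tris, s$u, model$r1r2, model$Ah,
                            model$mp, model$dirs)
    cg <- cap_grad(x)
    ru <- rr$res - s$P * as.vector(t(cg$g))
    # transverse penalty
    un <- rowSums(um * model$n_node)
    ru <- ru + as.vector(t(model$kappa * un * model$n_node))
    # rigid-body constraints (lumped)
    C1u <- colSums(model$w0 * um)
    m1 <- model$w0 * X
    C2u <- colSums(cbind(m1[, 2] * um[, 3] - m1[, 3] * um[, 2],
                         m1[, 3] * um[, 1] - m1[, 1] * um[, 3],
                         m1[, 1] * um[, 2] - m1[, 2] * um[, 1]))
    adj <- -(model$w0 %o% s$c1) -
      cbind(m1[, 3] * s$c2[2] - m1[, 2] * s$c2[3],
            m1[, 1] * s$c2[3] - m1[, 3] * s$c2[1],
            m1[, 2] * s$c2[1] - m1[, 1] * s$c2[2])
    ru <- ru + as.vector(t(adj))
    # ring in-plane constraints
    rn <- model$ring_nodes
    gvals <- rowSums(um[rn, , drop = FALSE] * model$ring_normals)
    for (k in seq_len(nr)) {
      n3 <- 3 * (rn[k] - 1)
      ru[n3 + 1:3] <- ru[n3 + 1:3] - s$lam[k] * model$ring_normals[k, ]
    }
    list(R = c(ru, -(cg$V - tgt_mm3), -C1u, -C2u, -gvals), gV = cg$g,
         V = cg$V)
  }

  x <- state
  rs <- resid(x)
  nrmf <- function(R) { v <- max(abs(R)); if (is.finite(v)) v else Inf }
  rn <- nrmf(rs$R)
  res0 <- max(rn, 1e-8)
  iters <- 0L; hist <- numeric(0)
  fact <- NULL; fact_age <- Inf
  repeat {
    vol_ok <- abs(rs$V - tgt_mm3) < ctl$vol_tol_ml * 1000
    if ((rn < ctl$rtol * res0 || rn < ctl$atol * (1 + res0) ||
         rn < ctl$floor) && vol_ok)
      return(c(x, list(converged = TRUE, iters = iters, hist = hist)))
    if (iters >= ctl$maxit)
      return(c(x, list(converged = FALSE, iters = iters, hist = hist)))
    if (is.null(fact) || fact_age >= 3) {
      tg <- memb_tangent_cpp(X, mesh$tris, x$u, model$r1r2, model$Ah,
                             model$mp, model$dirs)
      ii <- tg$i; jj <- tg$j; vv <- tg$x
      # penalty diagonal blocks
      for (d1 in 1:3) for (d2 in 1:3) {
        ii <- c(ii, 3 * (seq_len(N) - 1) + d1)
        jj <- c(jj, 3 * (seq_len(N) - 1) + d2)
        vv <- c(vv, model$kappa * model$n_node[, d1] * model$n_node[, d2])
      }
      # volume constraint: hessian -P d2V + border
      xdef <- X + matrix(x$u, ncol = 3, byrow = TRUE)
      if (x$P != 0) {
        ht <- .cav_hess_triplets(xdef, mesh$tris)
        ii <- c(ii, ht$i); jj <- c(jj, ht$j); vv <- c(vv, -x$P * ht$x)
        # cap hessian blocks: d2 det(a,b,c)/db dc = -skew(a)
        for (r in mesh$rings) {
          idx <- r$nodes; nxt <- idx[c(2:length(idx), 1)]
          sgn <- if (isTRUE(r$flip_cap)) -1 else 1
          a <- r$apex
          for (kk in seq_along(idx)) {
            nb <- idx[kk]; nc <- nxt[kk]
            Sk <- -.skew(a) / 6
            for (r2 in 1:3) for (c2 in 1:3) {
              if (Sk[r2, c2] == 0) next
              ii <- c(ii, 3 * (nb - 1) + r2, 3 * (nc - 1) + c2)
              jj <- c(jj, 3 * (nc - 1) + c2, 3 * (nb - 1) + r2)
              vv <- c(vv, -x$P * sgn * Sk[r2, c2], -x$P * sgn * Sk[r2, c2])
            }
          }
        }
      }
      gv <- as.vector(t(rs$gV))
      nz <- which(gv != 0)
      ii <- c(ii, nz, rep(P_id, length(nz)))
      jj <- c(jj, rep(P_id, length(nz)), nz)
      vv <- c(vv, -gv[nz], -gv[nz])
      # rigid borders
      m1 <- model$w0 * X
      cols <- list(cbind(model$w0, 0, 0), cbind(0, model$w0, 0),
                   cbind(0, 0, model$w0),
                   cbind(0, -m1[, 3], m1[, 2]),
                   cbind(m1[, 3], 0, -m1[, 1]),
                   cbind(-m1[, 2], m1[, 1], 0))
      for (d in 1:6) {
        colv <- as.vector(t(cols[[d]]))
        nz <- which(colv != 0)
        ii <- c(ii, nz, rep(c_ids[d], length(nz)))
        jj <- c(jj, rep(c_ids[d], length(nz)), nz)
        vv <- c(vv, -colv[nz], -colv[nz])
      }
      # ring rows
      rnod <- model$ring_nodes
      for (k in seq_len(nr)) {
        n3 <- 3 * (rnod[k] - 1)
        ii <- c(ii, n3 + 1:3, rep(r_ids[k], 3))
        jj <- c(jj, rep(r_ids[k], 3), n3 + 1:3)
        vv <- c(vv, -model$ring_normals[k, ], -model$ring_normals[k, ])
      }
      A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
      # vessel systems are small; sparse LU is robust to the weakly
      # penalized bending modes where an unpivoted LDL' loses accuracy
      fact <- list(kind = "lu", f = Matrix::lu(A))
      fact_age <- 0
    }
    dx <- tryCatch(.kkt_solve(fact, -rs$R), error = function(e) NULL)
    if (is.null(dx)) {
      if (fact_age == 0) return(c(x, list(converged = FALSE, iters = iters,
                                          hist = hist)))
      fact <- NULL; next
    }
    alpha <- 1; rsn <- NULL
    repeat {
      xn <- x
      xn$u <- x$u + alpha * dx[seq_len(3 * N)]
      xn$P <- x$P + alpha * dx[P_id]
      xn$c1 <- x$c1 + alpha * dx[c_ids[1:3]]
      xn$c2 <- x$c2 + alpha * dx[c_ids[4:6]]
      if (nr > 0) xn$lam <- x$lam + alpha * dx[r_ids]
      rsn <- resid(xn)
      if (is.finite(nrmf(rsn$R)) &&
          (nrmf(rsn$R) < rn * (1 - 1e-4 * alpha) || alpha < 0.05)) break
      alpha <- alpha / 2
      if (alpha < 1 / 128) break
    }
    if (!is.finite(nrmf(rsn$R))) {
      if (fact_age > 0) { fact <- NULL; next }
      return(c(x, list(converged = FALSE, iters = iters, hist = hist)))
    }
    improved <- nrmf(rsn$R) < rn
    if (!improved && fact_age > 0) { fact <- NULL; next }
    x <- xn; rs <- rsn; rn <- nrmf(rs$R)
    hist <- c(hist, rn); iters <- iters + 1L; fact_age <- fact_age + 1
  }
}

#' Von Mises stress field of a vessel solve
#'
#' Plane-stress von Mises invariant of the membrane Cauchy stress per cell,
#' its area-weighted average, and the maximum with its location.
#'
#' @param result A `vessel_solve_result`.
#' @param model The `vessel_model`.
#' @return List with per-cell tibble `cells`, `average`, `max`, and the
#'   mesh region containing the maximum (`max_region`).
#' @export
von_mises_field <- function(result, model) {
  vm <- result$vm
  A <- model$Aref
  cells <- tibble::tibble(region = model$mesh$region, vm = vm, area = A,
                          s1 = result$s1, s2 = result$s2)
  imax <- which.max(vm)
  list(cells = cells,
       average = sum(vm * A) / sum(A),
       max = vm[imax],
       max_element = imax,
       max_region = model$mesh$region[imax])
}

#' Pressure-volume response curve of a vessel by FE inflation
#'
#' Solves the membrane at a ramp of cavity volumes and returns the curve
#' with monotone spline interpolants for pressure, average/maximum von
#' Mises stress and slice diameters.  Because the membrane is elastic and
#' history-independent, evaluating these interpolants is equivalent to a
#' per-step FE solve up to interpolation error.
#'
#' @param model A `vessel_model`.
#' @param P_max Ramp until the lumen pressure exceeds this value, Pa
#'   (default 16 kPa, about 120 mmHg), so the sampled range adapts to the
#'   wall stiffness.
#' @param dV_frac Volume increment per ramp point, as a fraction of the
#'   reference volume.
#' @param V_max Hard upper bound of the ramp, ml (default 3 x reference).
#' @return A `vessel_pv_curve`: tibble `curve` plus function `P(V)` and
#'   lookups for stresses/diameters.
#' @export
vessel_pv_curve <- function(model, P_max = 16e3, dV_frac = 0.06,
                            V_max = NULL) {
  V0 <- model$mesh$ref_volume
  if (is.null(V_max)) V_max <- 3 * V0
  state <- NULL
  rows <- list()
  sl_names <- names(model$mesh$slices)
  Vk <- V0
  repeat {
    res <- solve_vessel_pressure(model, Vk, state = state)
    state <- res$state
    vmf <- von_mises_field(res, model)
    dd <- vapply(sl_names, function(s)
      diameter_at_slice(model$mesh, res$u, s), numeric(1))
    rows[[length(rows) + 1]] <-
      tibble::tibble(V = Vk, P = res$P, vm_avg = vmf$average,
                     vm_max = vmf$max,
                     !!!stats::setNames(as.list(dd),
                                        paste0("diam_", sl_names)))
    if (res$P >= P_max || Vk >= V_max) break
    Vk <- min(Vk + dV_frac * V0, V_max)
  }
  curve <- dplyr::bind_rows(rows)
  mono <- function(y) stats::splinefun(curve$V, y, method = "monoH.FC")
  structure(list(curve = curve, P = mono(curve$P),
                 vm_avg = mono(curve$vm_avg), vm_max = mono(curve$vm_max),
                 diam = lapply(stats::setNames(sl_names, sl_names),
                               function(s) mono(curve[[paste0("diam_", s)]])),
                 V_range = range(curve$V), model_ref_volume = V0),
            class = "vessel_pv_curve")
}

#' @export
#' @method print vessel_solve_result
print.vessel_solve_result <- function(x, ...) {
  cat(sprintf("Vessel FE solve: P = %.1f Pa (%.2f mmHg) at V = %.2f ml (%d iters)\n",
              x$P, x$P / 133.322, x$volume, x$newton_iters))
  invisible(x)
}
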