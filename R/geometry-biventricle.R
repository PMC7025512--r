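# Programmatic idealized cardiac geometries: a truncated-ellipsoid
# biventricle (LV free wall / septum / RV free wall with a crescent RV
# cavity) and spherical shells, meshed with linear tetrahedra by extruding a
# structured surface grid transmurally and splitting the prisms with a
# face-diagonal rule that guarantees conforming tetrahedra.
#
# Lengths in mm; cavity volumes reported in ml (1 ml = 1000 mm^3).

# ---- prism -> 3 conforming tets (smallest-global-index diagonal rule) ----
# For each rectangular prism face the diagonal is taken from the face vertex
# with the smallest global index; choosing the prism's smallest vertex as the
# local origin makes the decomposition unique and face-compatible between
# neighbouring prisms.
.prism_rotations <- list(
  c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
  c(4, 6, 5, 1, 3, 2), c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))

.prism_to_tets <- function(p) {
  k <- which.min(p)
  rot <- .prism_rotations[[k]]
  q <- p[rot]
  # now q[1] is the global minimum; diagonals q1-q5 and q1-q6 are forced
  if (min(q[2], q[6]) < min(q[3], q[5])) {
    # face (q2,q3,q6,q5) diagonal q2-q6
    rbind(c(q[1], q[2], q[3], q[6]),
          c(q[1], q[2], q[6], q[5]),
          c(q[1], q[5], q[6], q[4]))
  } else {
    rbind(c(q[1], q[2], q[3], q[5]),
          c(q[1], q[3], q[6], q[5]),
          c(q[1], q[5], q[6], q[4]))
  }
}

.prisms_to_tets <- function(prisms) {
  do.call(rbind, lapply(seq_len(nrow(prisms)),
                        function(i) .prism_to_tets(prisms[i, ])))
}

# signed volume x6 of tets given node matrix
.tet_vol6 <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
    b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
    b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])
}

.fix_tet_orientation <- function(nodes, tets) {
  v6 <- .tet_vol6(nodes, tets)
  flip <- v6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(abs(v6) < 1e-12)) stop("degenerate tetrahedron generated")
  tets
}

# ---- structured surface grid of a surface of revolution -----------------
# s in [s0, s1] (s0 = 0 collapses to an apex point), theta 0..2pi periodic.
# Returns node parameter table and a consistent triangulation.
.rev_surface_grid <- function(n_theta, n_s, apex = TRUE) {
  stopifnot(n_theta >= 6, n_s >= 2)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  id <- function(i, j) {            # ring i (1..n_s), theta index j (1-based, wraps)
    jj <- ((j - 1) %% n_theta) + 1
    (if (apex) 1L else 0L) + (i - 1L) * n_theta + jj
  }
  tris <- list(); param <- list()
  if (apex) param[[1]] <- c(i = 0, j = NA)
  for (i in seq_len(n_s)) for (j in seq_len(n_theta))
    param[[id(i, j)]] <- c(i = i, j = j)
  if (apex) {
    for (j in seq_len(n_theta))
      tris[[length(tris) + 1]] <- c(1L, id(1, j + 1), id(1, j))
  }
  for (i in seq_len(n_s - 1)) for (j in seq_len(n_theta)) {
    a <- id(i, j); b <- id(i, j + 1); c <- id(i + 1, j + 1); d <- id(i + 1, j)
    tris[[length(tris) + 1]] <- c(a, b, c)
    tris[[length(tris) + 1]] <- c(a, c, d)
  }
  list(n_nodes = (if (apex) 1L else 0L) + n_s * n_theta,
       tris = do.call(rbind, tris),
       param = do.call(rbind, param),
       id = id, theta = theta)
}

#' Fixture specification for the idealized biventricle
#'
#' The LV is a truncated (basal plane z = 0) thick-walled half-ellipsoid; the
#' RV cavity is a crescent-shaped gap between the LV epicardium and an
#' attached RV free wall shell spanning a circumferential sector.  Cavity
#' sizes default to the measured end-diastolic volumes (LV 72 ml, RV 77 ml).
#'
#' @param lv_volume_ml Target LV cavity volume at reference, ml.
#' @param rv_volume_ml Target RV cavity volume at reference, ml.
#' @param c_endo LV endocardial long semi-axis, mm (apex depth below base).
#' @param t_lv LV wall thickness, mm.
#' @param t_rv RV free wall thickness, mm.
#' @param rv_theta Circumferential sector of the RV attachment, radians
#'   (length-2).
#' @param rv_s_frac Fraction of the apex-to-base arc below which the RV
#'   cavity does not extend.
#' @param n_theta,n_s Circumferential / longitudinal surface resolution.
#' @param n_xi,n_xi_rv Transmural layers of the LV wall / RV free wall.
#' @param endo_angle,epi_angle Helix angles of the rule-based fiber field,
#'   degrees.
#' @return A `bv_spec` list.
#' @export
bv_spec <- function(lv_volume_ml = 72, rv_volume_ml = 77, c_endo = 55,
                    t_lv = 9, t_rv = 5,
                    rv_theta = c(0.45 * pi, 1.55 * pi), rv_s_frac = 0.35,
                    n_theta = 32, n_s = 16, n_xi = 2, n_xi_rv = 2,
                    endo_angle = 60, epi_angle = -60) {
  stopifnot(lv_volume_ml > 0, rv_volume_ml > 0, c_endo > 0, t_lv > 0,
            t_rv > 0, n_theta %% 2 == 0, n_s >= 4, n_xi >= 1, n_xi_rv >= 1,
            rv_theta[2] > rv_theta[1])
  if (lv_volume_ml < 20 || lv_volume_ml > 150)
    stop("LV cavity volume outside the supported 20-150 ml range",
         call. = FALSE)
  structure(list(lv_volume_ml = lv_volume_ml, rv_volume_ml = rv_volume_ml,
                 c_endo = c_endo, t_lv = t_lv, t_rv = t_rv,
                 rv_theta = rv_theta, rv_s_frac = rv_s_frac,
                 n_theta = n_theta, n_s = n_s, n_xi = n_xi,
                 n_xi_rv = n_xi_rv,
                 endo_angle = endo_angle, epi_angle = epi_angle),
            class = "bv_spec")
}

#' Coarse biventricle spec for in-loop finite-element runs
#'
#' @param ... Overrides passed to [bv_spec()].
#' @return A `bv_spec`.
#' @export
bv_spec_coarse <- function(...) {
  args <- utils::modifyList(list(n_theta = 12, n_s = 6, n_xi = 1,
                                 n_xi_rv = 1, rv_theta = c(0.3 * pi, 1.7 * pi),
                                 rv_s_frac = 0.2), list(...))
  do.call(bv_spec, args)
}

# analytic truncated-ellipsoid (half-ellipsoid) volume in ml
.half_ellipsoid_ml <- function(a, c) (2 / 3) * pi * a^2 * c / 1000

# closed-surface volume in ml from oriented triangles
.surface_volume_ml <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c <- nodes[tris[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(s) / 6 / 1000
}

#' Generate the idealized biventricular mesh
#'
#' Builds a conforming linear tetrahedral mesh with cells labelled `LVFW`,
#' `SEPTUM` (LV wall under the RV attachment sector) and `RVFW`, closed
#' endocardial surface triangulations for both cavities (basal closure in
#' the z = 0 plane contributes no volume because basal motion is in-plane),
#' the per-cell normalized transmural depth and local
#' (circumferential, longitudinal, transmural) frames, and the rule-based
#' transmural fiber field.
#'
#' @param spec A [bv_spec()].
#' @return A `bv_mesh` object.
#' @export
make_biventricle <- function(spec = bv_spec()) {
  a_en <- sqrt(spec$lv_volume_ml * 1000 / ((2 / 3) * pi * spec$c_endo))
  c_en <- spec$c_endo
  a_ep <- a_en + spec$t_lv; c_ep <- c_en + spec$t_lv
  nt <- spec$n_theta; ns <- spec$n_s; nxi <- spec$n_xi
  g <- .rev_surface_grid(nt, ns, apex = TRUE)
  svals <- (pi / 2) * (0:ns) / ns          # s = 0 apex ... pi/2 base
  nsurf <- g$n_nodes

  # LV wall 3D nodes: layers xi = 0..1, ellipsoid (a_en + xi t, c_en + xi t)
  lv_node_id <- function(sn, k) sn + k * nsurf       # k = 0..nxi
  nodes <- matrix(0, nsurf * (nxi + 1), 3)
  npar <- matrix(NA_real_, nsurf * (nxi + 1), 3)     # theta, s, xi
  for (k in 0:nxi) {
    xi <- k / nxi
    a <- a_en + xi * spec$t_lv; c <- c_en + xi * spec$t_lv
    for (sn in seq_len(nsurf)) {
      pp <- g$param[sn, ]
      if (pp["i"] == 0) { th <- NA; s <- 0 } else {
        th <- g$theta[pp["j"]]; s <- svals[pp["i"] + 1]
      }
      x <- if (is.na(th)) c(0, 0, -c) else
        c(a * sin(s) * cos(th), a * sin(s) * sin(th), -c * cos(s))
      nodes[lv_node_id(sn, k), ] <- x
      npar[lv_node_id(sn, k), ] <- c(ifelse(is.na(th), 0, th), s, xi)
    }
  }

  prisms <- list(); pregion <- list(); pxi <- list()
  for (k in 0:(nxi - 1)) for (ti in seq_len(nrow(g$tris))) {
    tr <- g$tris[ti, ]
    prisms[[length(prisms) + 1]] <-
      c(lv_node_id(tr, k), lv_node_id(tr, k + 1))
    pregion[[length(pregion) + 1]] <- "LV"
    pxi[[length(pxi) + 1]] <- (k + 0.5) / nxi
  }

  # ---- RV free wall ----
  th1 <- spec$rv_theta[1]; th2 <- spec$rv_theta[2]
  i_min <- max(2L, ceiling(spec$rv_s_frac * ns))
  sector_j <- which(g$theta >= th1 - 1e-9 & g$theta <= th2 + 1e-9)
  if (length(sector_j) < 5) stop("RV sector too narrow for this n_theta")
  j1 <- min(sector_j); j2 <- max(sector_j)
  in_sector <- function(i, j) i >= i_min && j >= j1 && j <= j2
  # interior nodes (gap > 0): at least one index away from the sector rim
  interior <- function(i, j) i >= i_min + 2 && j >= j1 + 2 && j <= j2 - 2 &&
    i <= ns  # base row i = ns is open (cavity capped by the basal plane)

  gap_shape <- function(i, j) {
    if (!interior(i, j)) return(0)
    span_j <- (j2 - 2) - (j1 + 2)
    fj <- if (span_j <= 0) 1 else sin(pi * (j - (j1 + 1)) / (span_j + 2))
    fi <- sin(pmin(1, (i - (i_min + 2) + 1) / max(1, (ns - 1) - (i_min + 2)))
              * pi / 2)
    (fj^0.7) * (fi^0.7)
  }
  epi_normal <- function(x) {
    n <- c(x[1] / a_ep^2, x[2] / a_ep^2, x[3] / c_ep^2)
    n / sqrt(sum(n^2))
  }

  sector_nodes <- list()                 # (i, j) -> epi surface-node index
  for (i in i_min:ns) for (j in j1:j2)
    sector_nodes[[paste(i, j)]] <- g$id(i, j)

  build_rv <- function(g0) {
    nodes_loc <- nodes; npar_loc <- npar
    inner_id <- outer_id <- list()
    nxirv <- spec$n_xi_rv
    lay_ids <- vector("list", nxirv + 1)
    for (key in names(sector_nodes)) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      sn <- sector_nodes[[key]]
      epi3 <- lv_node_id(sn, nxi)
      x0 <- nodes_loc[epi3, ]
      nrm <- epi_normal(x0)
      gv <- g0 * gap_shape(ij[1], ij[2])
      for (L in 0:nxirv) {
        off <- gv + (L / nxirv) * spec$t_rv
        if (L == 0 && gv == 0) {
          lay_ids[[1]][[key]] <- epi3
        } else {
          nodes_loc <- rbind(nodes_loc, x0 + off * nrm)
          npar_loc <- rbind(npar_loc, c(npar_loc[epi3, 1:2], L / nxirv))
          lay_ids[[L + 1]][[key]] <- nrow(nodes_loc)
        }
      }
    }
    list(nodes = nodes_loc, npar = npar_loc, lay = lay_ids)
  }

  # RV cavity volume for a given maximal gap (epi sector reversed + inner)
  sector_tris <- {
    keep <- apply(g$tris, 1, function(tr) {
      all(vapply(tr, function(sn) {
        pp <- g$param[sn, ]; pp["i"] > 0 && in_sector(pp["i"], pp["j"])
      }, logical(1)))
    })
    g$tris[keep, , drop = FALSE]
  }
  if (nrow(sector_tris) < 4) stop("RV sector resolution too coarse")

  rv_cavity_vol <- function(built) {
    inner_tri <- t(apply(sector_tris, 1, function(tr) {
      vapply(tr, function(sn) {
        pp <- g$param[sn, ]
        built$lay[[1]][[paste(pp["i"], pp["j"])]]
      }, numeric(1))
    }))
    epi_tri <- t(apply(sector_tris, 1, function(tr) lv_node_id(tr, nxi)))
    # inner surface keeps the epi orientation (outward); reversed epi closes it
    v <- .surface_volume_ml(built$nodes, inner_tri) -
      .surface_volume_ml(built$nodes, epi_tri)
    abs(v)
  }

  f_target <- function(g0) rv_cavity_vol(build_rv(g0)) - spec$rv_volume_ml
  g0 <- tryCatch(stats::uniroot(f_target, c(0.5, 200), tol = 1e-4)$root,
                 error = function(e)
                   stop("RV sector cannot reach the target cavity volume ",
                        "at this resolution; widen rv_theta, lower ",
                        "rv_s_frac or refine the grid", call. = FALSE))
  built <- build_rv(g0)
  nodes <- built$nodes; npar <- built$npar

  nxirv <- spec$n_xi_rv
  for (L in 0:(nxirv - 1)) for (ti in seq_len(nrow(sector_tris))) {
    tr <- sector_tris[ti, ]
    keys <- apply(g$param[tr, , drop = FALSE], 1,
                  function(pp) paste(pp["i"], pp["j"]))
    lo <- vapply(keys, function(k) built$lay[[L + 1]][[k]], numeric(1))
    hi <- vapply(keys, function(k) built$lay[[L + 2]][[k]], numeric(1))
    prisms[[length(prisms) + 1]] <- c(lo, hi)
    pregion[[length(pregion) + 1]] <- "RVFW"
    pxi[[length(pxi) + 1]] <- (L + 0.5) / nxirv
  }

  prisms <- do.call(rbind, prisms)
  tets <- .prisms_to_tets(prisms)
  region3 <- rep(unlist(pregion), each = 3)
  xi3 <- rep(unlist(pxi), each = 3)
  tets <- .fix_tet_orientation(nodes, tets)

  # LV cells under the RV sector are septum
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
             nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  thc <- atan2(cent[, 2], cent[, 1]); thc <- ifelse(thc < 0, thc + 2 * pi, thc)
  s_lo <- svals[i_min]
  zc <- -c_en * cos(s_lo)                 # z below which no septum label
  region <- ifelse(region3 == "RVFW", "RVFW",
                   ifelse(thc >= th1 & thc <= th2 & cent[, 3] >= zc,
                          "SEPTUM", "LVFW"))

  # local frames per cell (surface-of-revolution approximation)
  e_c <- cbind(-cent[, 2], cent[, 1], 0)
  e_c <- e_c / sqrt(rowSums(e_c^2))
  nrm <- cbind(cent[, 1] / a_ep^2, cent[, 2] / a_ep^2, cent[, 3] / c_ep^2)
  nrm <- nrm - rowSums(nrm * e_c) * e_c
  e_t <- nrm / sqrt(rowSums(nrm^2))
  e_l <- cbind(e_t[, 2] * e_c[, 3] - e_t[, 3] * e_c[, 2],
               e_t[, 3] * e_c[, 1] - e_t[, 1] * e_c[, 3],
               e_t[, 1] * e_c[, 2] - e_t[, 2] * e_c[, 1])

  # cavity surfaces
  endo_tri <- t(apply(g$tris, 1, function(tr) lv_node_id(tr, 0)))
  if (.surface_volume_ml(nodes, endo_tri) < 0) endo_tri <- endo_tri[, c(1, 3, 2)]
  inner_tri <- t(apply(sector_tris, 1, function(tr) {
    vapply(tr, function(sn) {
      pp <- g$param[sn, ]; built$lay[[1]][[paste(pp["i"], pp["j"])]]
    }, numeric(1))
  }))
  epi_tri <- t(apply(sector_tris, 1, function(tr) lv_node_id(tr, nxi)))
  rv_surf <- rbind(inner_tri, epi_tri[, c(1, 3, 2)])
  if (.surface_volume_ml(nodes, rv_surf) < 0)
    rv_surf <- rv_surf[, c(1, 3, 2)]

  base_nodes <- which(abs(nodes[, 3]) < 1e-8)

  mesh <- structure(list(
    nodes = nodes, tets = tets, region = region, depth = xi3,
    frame = list(e_c = e_c, e_l = e_l, e_t = e_t),
    cavities = list(LV = endo_tri, RV = rv_surf),
    base_nodes = base_nodes,
    lv_volume_analytic = .half_ellipsoid_ml(a_en, c_en),
    dims = list(a_endo = a_en, c_endo = c_en, a_epi = a_ep, c_epi = c_ep,
                gap_max = g0),
    spec = spec), class = "bv_mesh")
  mesh$cavity_volumes <- c(LV = .surface_volume_ml(nodes, endo_tri),
                           RV = .surface_volume_ml(nodes, rv_surf))
  assign_transmural_fibers(mesh, spec$endo_angle, spec$epi_angle)
}

#' Helix angle of the rule-based fiber field
#'
#' Linear in the normalized transmural depth: `endo_angle` at depth 0
#' (endocardium) to `epi_angle` at depth 1 (epicardium).
#'
#' @param depth Normalized wall depth in [0, 1] (vectorised).
#' @param endo_angle,epi_angle Helix angles at the surfaces, degrees.
#' @return Helix angle in degrees.
#' @export
helix_angle <- function(depth, endo_angle = 60, epi_angle = -60) {
  endo_angle + (epi_angle - endo_angle) * depth
}

#' Assign a rule-based transmural fiber field
#'
#' The myofiber direction makes the helix angle [helix_angle()] with the
#' local circumferential direction, rotated in the tangent
#' (circumferential, longitudinal) plane; the sheet direction is transmural
#' and the sheet-normal completes the right-handed orthonormal basis.
#'
#' @param mesh A `bv_mesh` (with per-cell depth and local frames).
#' @param endo_angle,epi_angle Helix angles at endo-/epicardium, degrees.
#' @return The mesh with per-cell `fibers` (matrices `f`, `s`, `n`).
#' @export
assign_transmural_fibers <- function(mesh, endo_angle = 60, epi_angle = -60) {
  al <- helix_angle(mesh$depth, endo_angle, epi_angle) * pi / 180
  f <- cos(al) * mesh$frame$e_c + sin(al) * mesh$frame$e_l
  s <- mesh$frame$e_t
  n <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
             f[, 3] * s[, 1] - f[, 1] * s[, 3],
             f[, 1] * s[, 2] - f[, 2] * s[, 1])
  mesh$fibers <- list(f = f, s = s, n = n)
  mesh$fiber_angles <- al * 180 / pi
  mesh
}

#' Thick-walled spherical shell mesh (single cavity)
#'
#' A latitude-longitude sphere surface extruded radially; used as the
#' single-cavity analog for verifying the chamber solver against the
#' incompressible thick-shell quadrature solution.
#'
#' @param r_inner Inner radius, mm.
#' @param thickness Wall thickness, mm.
#' @param n_theta,n_s Surface resolution (longitudes, latitude bands).
#' @param n_xi Transmural layers.
#' @return A `bv_mesh` with a single cavity named `LV`, no basal plane and
#'   tangential fibers.
#' @export
make_sphere_shell <- function(r_inner = 20, thickness = 4, n_theta = 16,
                              n_s = 8, n_xi = 2) {
  stopifnot(r_inner > 0, thickness > 0, n_s >= 4)
  nt <- n_theta; ns <- n_s
  theta <- 2 * pi * (seq_len(nt) - 1) / nt
  svals <- pi * (0:ns) / ns
  # surface nodes: 2 poles + (ns-1) rings
  nsurf <- 2L + (ns - 1L) * nt
  sid <- function(i, j) {     # i = 0..ns (0 south pole, ns north), j wraps
    if (i == 0) return(1L)
    if (i == ns) return(2L)
    jj <- ((j - 1) %% nt) + 1
    2L + (i - 1L) * nt + jj
  }
  tris <- list()
  for (j in seq_len(nt)) {
    tris[[length(tris) + 1]] <- c(sid(0, 1), sid(1, j + 1), sid(1, j))
    tris[[length(tris) + 1]] <- c(sid(ns, 1), sid(ns - 1, j), sid(ns - 1, j + 1))
  }
  for (i in seq_len(ns - 2)) for (j in seq_len(nt)) {
    a <- sid(i, j); b <- sid(i, j + 1); c <- sid(i + 1, j + 1); d <- sid(i + 1, j)
    tris[[length(tris) + 1]] <- c(a, b, c)
    tris[[length(tris) + 1]] <- c(a, c, d)
  }
  tris <- do.call(rbind, tris)

  usurf <- matrix(0, nsurf, 3)
  usurf[1, ] <- c(0, 0, -1); usurf[2, ] <- c(0, 0, 1)
  for (i in seq_len(ns - 1)) for (j in seq_len(nt))
    usurf[sid(i, j), ] <- c(sin(svals[i + 1]) * cos(theta[j]),
                            sin(svals[i + 1]) * sin(theta[j]),
                            -cos(svals[i + 1]))

  nid <- function(sn, k) sn + k * nsurf
  nodes <- matrix(0, nsurf * (n_xi + 1), 3)
  for (k in 0:n_xi)
    nodes[nid(seq_len(nsurf), k), ] <- usurf * (r_inner + k / n_xi * thickness)

  prisms <- list(); pxi <- list()
  for (k in 0:(n_xi - 1)) for (ti in seq_len(nrow(tris))) {
    tr <- tris[ti, ]
    prisms[[length(prisms) + 1]] <- c(nid(tr, k), nid(tr, k + 1))
    pxi[[length(pxi) + 1]] <- (k + 0.5) / n_xi
  }
  prisms <- do.call(rbind, prisms)
  tets <- .prisms_to_tets(prisms)
  xi3 <- rep(unlist(pxi), each = 3)
  tets <- .fix_tet_orientation(nodes, tets)

  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
             nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  e_t <- cent / sqrt(rowSums(cent^2))
  up <- matrix(rep(c(0, 0, 1), each = nrow(cent)), ncol = 3)
  polar <- abs(e_t[, 3]) > 0.95
  up[polar, ] <- matrix(rep(c(1, 0, 0), each = sum(polar)), ncol = 3)
  e_c <- cbind(up[, 2] * e_t[, 3] - up[, 3] * e_t[, 2],
               up[, 3] * e_t[, 1] - up[, 1] * e_t[, 3],
               up[, 1] * e_t[, 2] - up[, 2] * e_t[, 1])
  e_c <- e_c / sqrt(rowSums(e_c^2))
  e_l <- cbind(e_t[, 2] * e_c[, 3] - e_t[, 3] * e_c[, 2],
               e_t[, 3] * e_c[, 1] - e_t[, 1] * e_c[, 3],
               e_t[, 1] * e_c[, 2] - e_t[, 2] * e_c[, 1])

  inner_tri <- tris
  if (.surface_volume_ml(nodes, inner_tri) < 0) inner_tri <- inner_tri[, c(1, 3, 2)]

  mesh <- structure(list(
    nodes = nodes, tets = tets,
    region = rep("WALL", nrow(tets)), depth = xi3,
    frame = list(e_c = e_c, e_l = e_l, e_t = e_t),
    cavities = list(LV = inner_tri),
    base_nodes = integer(0),
    dims = list(r_inner = r_inner, thickness = thickness),
    spec = list(kind = "sphere_shell")), class = "bv_mesh")
  mesh$cavity_volumes <- c(LV = .surface_volume_ml(nodes, inner_tri))
  assign_transmural_fibers(mesh, 0, 0)
}

#' @export
#' @method print bv_mesh
print.bv_mesh <- function(x, ...) {
  cat("Biventricular-type tetrahedral mesh\n")
  cat(sprintf("  nodes: %d, tets: %d\n", nrow(x$nodes), nrow(x$tets)))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  cat("  cavity volumes (ml):",
      paste(sprintf("%s = %.2f", names(x$cavity_volumes), x$cavity_volumes),
            collapse = ", "), "\n")
  invisible(x)
}
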