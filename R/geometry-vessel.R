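# Idealized membrane artery surfaces: straight cylinders and symmetric
# bifurcations ("pair of pants" stitching), triangulated with ring node sets,
# per-element local (longitudinal, circumferential) frames for the fiber
# families, and flat virtual caps used only for cavity-volume computation.
#
# Lengths in mm, volumes reported in ml.

#' Fixture specification for a membrane vessel
#'
#' @param kind `"cylinder"` or `"bifurcation"`.
#' @param radius Tube radius (parent radius for a bifurcation), mm.
#' @param length Tube length (parent length for a bifurcation), mm.
#' @param child_radius,child_length Branch dimensions for a bifurcation, mm.
#' @param branch_angle Half-angle between a branch axis and the parent axis,
#'   degrees.
#' @param h Membrane thickness, mm.
#' @param n_theta Circumferential resolution (multiple of 4).
#' @param n_z Axial resolution of the (parent) tube.
#' @param alpha Diagonal fiber-family angle, degrees.
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(kind = c("cylinder", "bifurcation"), radius = 10,
                        length = 60, child_radius = 0.75 * radius,
                        child_length = 0.6 * length, branch_angle = 32,
                        h = 1.5, n_theta = 20, n_z = 12, alpha = 45) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, length > 0, h > 0, n_theta %% 4 == 0, n_z >= 3)
  structure(list(kind = kind, radius = radius, length = length,
                 child_radius = child_radius, child_length = child_length,
                 branch_angle = branch_angle, h = h, n_theta = n_theta,
                 n_z = n_z, alpha = alpha), class = "vessel_spec")
}

#' Generate a membrane vessel mesh from a spec
#'
#' @param spec A [vessel_spec()].
#' @return A `vessel_mesh`.
#' @export
make_vessel <- function(spec) {
  if (spec$kind == "cylinder")
    make_cylinder(spec$radius, spec$length, h = spec$h,
                  n_theta = spec$n_theta, n_z = spec$n_z)
  else
    make_bifurcation(spec$radius, spec$child_radius, spec$length,
                     spec$child_length, spec$branch_angle, h = spec$h,
                     n_theta = spec$n_theta, n_z = spec$n_z)
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

.as_disp_matrix <- function(u) {
  if (is.matrix(u)) u else matrix(u, ncol = 3, byrow = TRUE)
}

# greedy strip triangulation between two open polylines (index vectors)
.stitch_strip <- function(A, B) {
  fr <- function(v) (seq_along(v) - 1) / (length(v) - 1)
  fa <- fr(A); fb <- fr(B)
  i <- 1L; j <- 1L; tris <- list()
  while (i < length(A) || j < length(B)) {
    adv_a <- if (j == length(B)) TRUE
    else if (i == length(A)) FALSE
    else fa[i + 1] <= fb[j + 1]
    if (adv_a) {
      tris[[length(tris) + 1]] <- c(A[i], A[i + 1], B[j]); i <- i + 1L
    } else {
      tris[[length(tris) + 1]] <- c(A[i], B[j], B[j + 1]); j <- j + 1L
    }
  }
  do.call(rbind, tris)
}

.tri_centroids <- function(nodes, tris) {
  (nodes[tris[, 1], , drop = FALSE] + nodes[tris[, 2], , drop = FALSE] +
     nodes[tris[, 3], , drop = FALSE]) / 3
}

.tri_normals <- function(nodes, tris) {
  e1 <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  e2 <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

# build frames: project axis onto element plane (fall back to other axes
# where the surface normal is nearly parallel to the requested axis)
.element_frames <- function(nodes, tris, axes) {
  nrm <- .tri_normals(nodes, tris)
  e_l <- axes - rowSums(axes * nrm) * nrm
  len <- sqrt(rowSums(e_l^2))
  for (fb in list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))) {
    bad <- len < 0.2
    if (!any(bad)) break
    alt <- matrix(rep(fb, each = nrow(nrm)), ncol = 3)
    alt <- alt - rowSums(alt * nrm) * nrm
    e_l[bad, ] <- alt[bad, ]
    len <- sqrt(rowSums(e_l^2))
  }
  e_l <- e_l / len
  e_c <- cbind(nrm[, 2] * e_l[, 3] - nrm[, 3] * e_l[, 2],
               nrm[, 3] * e_l[, 1] - nrm[, 1] * e_l[, 3],
               nrm[, 1] * e_l[, 2] - nrm[, 2] * e_l[, 1])
  list(e_l = e_l, e_c = e_c, normal = nrm)
}

.vessel_finalize <- function(nodes, tris, region, axes, rings, slices, h,
                             dims) {
  # orient every triangle outward w.r.t. an interior reference point
  p_in <- dims$p_in
  nrm <- .tri_normals(nodes, tris)
  cent <- .tri_centroids(nodes, tris)
  ref <- matrix(rep(p_in, each = nrow(cent)), ncol = 3)
  flip <- rowSums(nrm * (cent - ref)) < 0
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]

  fr <- .element_frames(nodes, tris, axes)
  mesh <- structure(list(nodes = nodes, tris = tris, region = region,
                         h = h, frames = fr, rings = rings, slices = slices,
                         dims = dims), class = "vessel_mesh")
  mesh$ref_volume <- vessel_cavity_volume(mesh, u = NULL)
  if (mesh$ref_volume <= 0) stop("vessel surface orientation failed")
  mesh
}

#' Cavity volume of a membrane vessel
#'
#' Divergence-theorem volume of the deformed tube closed by flat virtual
#' caps fanned from a fixed apex point in each inlet/outlet ring plane
#' (rings are constrained to move in-plane, so the caps stay planar).
#'
#' @param mesh A `vessel_mesh`.
#' @param u Optional displacement matrix (N x 3) or vector (3N).
#' @return Volume in ml.
#' @export
vessel_cavity_volume <- function(mesh, u = NULL) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + .as_disp_matrix(u)
  v <- sum(.det3_rows(x, mesh$tris))
  for (r in mesh$rings) {
    idx <- r$nodes; nxt <- idx[c(2:length(idx), 1)]
    a <- matrix(rep(r$apex, each = length(idx)), ncol = 3)
    b <- x[idx, , drop = FALSE]; c <- x[nxt, , drop = FALSE]
    s <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    sgn <- if (isTRUE(r$flip_cap)) -1 else 1
    v <- v + sgn * sum(s)
  }
  v / 6 / 1000
}

.det3_rows <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c <- nodes[tris[, 3], , drop = FALSE]
  a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
}

# decide cap orientations once (so the closed volume is positive and each
# cap normal points along the ring's outward axis)
.fix_caps <- function(mesh) {
  for (k in seq_along(mesh$rings)) {
    r <- mesh$rings[[k]]
    idx <- r$nodes
    p1 <- mesh$nodes[idx[1], ]; p2 <- mesh$nodes[idx[2], ]
    n_fan <- .cross3(p1 - r$apex, p2 - r$apex)
    mesh$rings[[k]]$flip_cap <- sum(n_fan * r$normal) < 0
  }
  mesh
}

#' Straight-cylinder membrane vessel
#'
#' @param radius,length Tube dimensions, mm.
#' @param h Membrane thickness, mm.
#' @param n_theta,n_z Resolution.
#' @return A `vessel_mesh` along the z axis with inlet ring at z = 0 and
#'   outlet at z = `length`; reference cavity volume close to `pi r^2 L`.
#' @export
make_cylinder <- function(radius = 10, length = 60, h = 1.5, n_theta = 20,
                          n_z = 12) {
  stopifnot(n_theta %% 4 == 0)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  zz <- length * (0:n_z) / n_z
  id <- function(i, j) i * n_theta + ((j - 1) %% n_theta) + 1  # i = 0..n_z
  nodes <- do.call(rbind, lapply(0:n_z, function(i)
    cbind(radius * cos(th), radius * sin(th), zz[i + 1])))
  tris <- list()
  for (i in 0:(n_z - 1)) for (j in seq_len(n_theta)) {
    a <- id(i, j); b <- id(i, j + 1); c <- id(i + 1, j + 1); d <- id(i + 1, j)
    tris[[length(tris) + 1]] <- c(a, b, c)
    tris[[length(tris) + 1]] <- c(a, c, d)
  }
  tris <- do.call(rbind, tris)
  axes <- matrix(rep(c(0, 0, 1), each = nrow(tris)), ncol = 3)
  rings <- list(
    inlet = list(nodes = id(0, seq_len(n_theta)), normal = c(0, 0, -1),
                 point = c(0, 0, 0), apex = c(0, 0, 0)),
    outlet = list(nodes = id(n_z, seq_len(n_theta)), normal = c(0, 0, 1),
                  point = c(0, 0, length), apex = c(0, 0, length)))
  slices <- list(mid = list(point = c(0, 0, length / 2), normal = c(0, 0, 1)))
  dims <- list(radius = radius, length = length,
               p_in = c(0, 0, length / 2))
  mesh <- .vessel_finalize(nodes, tris, rep("tube", nrow(tris)), axes,
                           rings, slices, h, dims)
  .update_ref_volume(.fix_caps(mesh))
}

.update_ref_volume <- function(mesh) {
  mesh$ref_volume <- vessel_cavity_volume(mesh)
  mesh
}

#' Symmetric bifurcation membrane vessel
#'
#' A parent tube along z that splits into two straight branches in the
#' x-z plane, stitched watertight through a saddle ("pair of pants")
#' junction band.  One inlet ring (z = 0) and two outlet rings.
#'
#' @param r_parent,r_child Radii, mm.
#' @param l_parent,l_child Segment lengths, mm.
#' @param branch_angle Half-angle of each branch from the parent axis,
#'   degrees.
#' @param h Membrane thickness, mm.
#' @param n_theta Parent circumferential resolution (multiple of 4).
#' @param n_z Axial resolution per segment.
#' @return A `vessel_mesh` with regions `parent`, `right`, `left`,
#'   `junction`.
#' @export
make_bifurcation <- function(r_parent = 13, r_child = 9.5, l_parent = 40,
                             l_child = 32, branch_angle = 32, h = 1.2,
                             n_theta = 20, n_z = 8) {
  stopifnot(n_theta %% 4 == 0)
  N <- n_theta; M <- N / 2
  if (M %% 2 != 0) stop("n_theta must be a multiple of 4")
  beta <- branch_angle * pi / 180
  J <- c(0, 0, l_parent)

  nodes <- matrix(0, 0, 3); tris <- list(); region <- list(); axes <- list()
  add_nodes <- function(x) {
    nodes <<- rbind(nodes, x); (nrow(nodes) - nrow(x) + 1):nrow(nodes)
  }
  th <- 2 * pi * (seq_len(N) - 1) / N
  parent_ids <- matrix(0L, n_z + 1, N)
  for (i in 0:n_z) {
    z <- l_parent * i / n_z
    parent_ids[i + 1, ] <- add_nodes(cbind(r_parent * cos(th),
                                           r_parent * sin(th), z))
  }
  emit_band <- function(ids_lo, ids_hi, reg, axis) {
    n <- length(ids_lo)
    for (j in seq_len(n)) {
      jp <- (j %% n) + 1
      tris[[length(tris) + 1]] <<- c(ids_lo[j], ids_lo[jp], ids_hi[jp])
      tris[[length(tris) + 1]] <<- c(ids_lo[j], ids_hi[jp], ids_hi[j])
      region[[length(region) + 1]] <<- reg; region[[length(region) + 1]] <<- reg
      axes[[length(axes) + 1]] <<- axis; axes[[length(axes) + 1]] <<- axis
    }
  }
  for (i in seq_len(n_z))
    emit_band(parent_ids[i, ], parent_ids[i + 1, ], "parent", c(0, 0, 1))

  child <- function(sgn) {
    d <- c(sgn * sin(beta), 0, cos(beta))
    u_out <- c(sgn * cos(beta), 0, -sin(beta))
    t0 <- 1.25 * r_parent
    ids <- matrix(0L, n_z + 1, M)
    phi <- -pi / 2 + 2 * pi * (seq_len(M) - 1) / M
    for (i in 0:n_z) {
      tt <- t0 + (l_child - t0) * i / n_z
      ctr <- J + tt * d
      pts <- t(vapply(phi, function(p)
        ctr + r_child * (cos(p) * u_out + sin(p) * c(0, 1, 0)), numeric(3)))
      ids[i + 1, ] <- add_nodes(pts)
    }
    for (i in seq_len(n_z)) {
      # the first band past the stitch is still part of the branch-junction
      # transition zone (it contains the carina)
      reg <- if (i == 1) "junction" else if (sgn > 0) "right" else "left"
      emit_band(ids[i, ], ids[i + 1, ], reg, d)
    }
    list(ids = ids, d = d)
  }
  cr <- child(+1); cl <- child(-1)

  # junction stitching
  js1 <- N / 4 + 1          # theta = 90 deg  (+y saddle)
  js2 <- 3 * N / 4 + 1      # theta = 270 deg (-y saddle)
  top <- parent_ids[n_z + 1, ]
  right_arc <- top[c(js2:N, 1:js1)]                 # -y -> +y through +x
  left_arc <- top[js1:js2]                          # +y -> -y through -x
  kp <- M / 2 + 1                                   # +y split index (phi=pi/2)
  r_outer <- cr$ids[1, 1:kp]                        # -y -> +y (outer)
  r_inner <- cr$ids[1, c(kp:M, 1)]                  # +y -> -y (inner)
  l_outer <- rev(cl$ids[1, 1:kp])                   # +y -> -y (outer)
  l_inner <- cl$ids[1, c(kp:M, 1)]                  # +y -> -y (inner)

  add_tris <- function(tt, axis) {
    for (r in seq_len(nrow(tt))) {
      tris[[length(tris) + 1]] <<- tt[r, ]
      region[[length(region) + 1]] <<- "junction"
      axes[[length(axes) + 1]] <<- axis
    }
  }
  add_tris(.stitch_strip(right_arc, r_outer), cr$d)
  add_tris(.stitch_strip(left_arc, l_outer), cl$d)
  add_tris(.stitch_strip(r_inner, l_inner), c(0, 0, 1))
  S1 <- top[js1]; S2 <- top[js2]
  add_tris(rbind(c(S1, r_inner[1], l_inner[1])), c(0, 0, 1))
  add_tris(rbind(c(S2, r_inner[length(r_inner)], l_inner[length(l_inner)])),
           c(0, 0, 1))

  tris <- do.call(rbind, tris)
  region <- unlist(region)
  axes <- do.call(rbind, axes)

  end_ctr <- function(ch) J + ch$d * (l_child)
  rings <- list(
    inlet = list(nodes = parent_ids[1, ], normal = c(0, 0, -1),
                 point = c(0, 0, 0), apex = c(0, 0, 0)),
    outlet_right = list(nodes = cr$ids[n_z + 1, ], normal = cr$d,
                        point = end_ctr(cr), apex = end_ctr(cr)),
    outlet_left = list(nodes = cl$ids[n_z + 1, ], normal = cl$d,
                       point = end_ctr(cl), apex = end_ctr(cl)))
  slices <- list(mid_parent = list(point = c(0, 0, l_parent / 2),
                                   normal = c(0, 0, 1)))
  dims <- list(r_parent = r_parent, r_child = r_child, l_parent = l_parent,
               l_child = l_child, branch_angle = branch_angle,
               p_in = c(0, 0, 0.75 * l_parent))
  mesh <- .vessel_finalize(nodes, tris, region, axes, rings, slices, h, dims)
  .update_ref_volume(.fix_caps(mesh))
}

#' @export
#' @method print vessel_mesh
print.vessel_mesh <- function(x, ...) {
  cat("Membrane vessel mesh\n")
  cat(sprintf("  nodes: %d, triangles: %d, thickness: %.2f mm\n",
              nrow(x$nodes), nrow(x$tris), x$h))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  cat(sprintf("  rings: %d (%s)\n", length(x$rings),
              paste(names(x$rings), collapse = ", ")))
  cat(sprintf("  reference cavity volume: %.2f ml\n", x$ref_volume))
  invisible(x)
}

#' Effective diameter of a vessel cross-section
#'
#' Intersects the (possibly deformed) membrane surface with a plane and
#' returns the area-equivalent diameter `2 sqrt(A/pi)` of the enclosed
#' cross-section.
#'
#' @param mesh A `vessel_mesh`.
#' @param u Optional displacement (N x 3 matrix or 3N vector).
#' @param slice Name of a stored slice plane, or a
#'   `list(point =, normal =)`.
#' @return Diameter in mm.
#' @export
diameter_at_slice <- function(mesh, u = NULL, slice = 1) {
  sl <- if (is.list(slice) && !is.null(slice$point)) slice
  else mesh$slices[[slice]]
  if (is.null(sl)) stop("unknown slice plane", call. = FALSE)
  x <- mesh$nodes
  if (!is.null(u)) x <- x + .as_disp_matrix(u)
  nrm <- sl$normal / sqrt(sum(sl$normal^2))
  d <- drop(x %*% nrm) - sum(sl$point * nrm)
  area2 <- 0; n_seg <- 0L
  for (r in seq_len(nrow(mesh$tris))) {
    tr <- mesh$tris[r, ]; dv <- d[tr]
    if (all(dv > 0) || all(dv < 0)) next
    pts <- list()
    for (k in 1:3) {
      i1 <- tr[k]; i2 <- tr[(k %% 3) + 1]
      d1 <- d[i1]; d2 <- d[i2]
      if ((d1 > 0) != (d2 > 0)) {
        t <- d1 / (d1 - d2)
        pts[[length(pts) + 1]] <- x[i1, ] + t * (x[i2, ] - x[i1, ])
      }
    }
    if (length(pts) != 2) next
    # orient the segment so the curve runs counter-clockwise about nrm
    tn <- .tri_normals(x, mesh$tris[r, , drop = FALSE])[1, ]
    dir <- .cross3(nrm, tn)
    seg <- pts[[2]] - pts[[1]]
    if (sum(seg * dir) < 0) pts <- pts[c(2, 1)]
    p1 <- pts[[1]] - sl$point; p2 <- pts[[2]] - sl$point
    area2 <- area2 + sum(.cross3(p1, p2) * nrm)
    n_seg <- n_seg + 1L
  }
  if (n_seg < 3) stop("slice plane does not cut the surface in a closed curve",
                      call. = FALSE)
  A <- abs(area2) / 2
  2 * sqrt(A / pi)
}
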