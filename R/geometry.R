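#' @include AllClasses.R
NULL

# Plate Y positions (mm): plates lie in XZ (coronal) planes on the 40 mm
# fiducial grid, plate 1 most posterior (+Y, "bottom" with the patient
# supine) through plate 5 most anterior (-Y).
.plateY <- c(plate1 = 80, plate2 = 40, plate3 = 0, plate4 = -40, plate5 = -80)

# Structures mounted on the +Y ("bottom") face of a plate sit with their
# sphere centres offset 14 mm from the plate plane (half plate thickness +
# mounting stud + sphere radius); value chosen so 20 mm OD array spheres
# clear the 10 mm fiducials on the neighbouring grid plane.
.mountOffsetY <- 14

#' Build the 57-sphere fiducial lattice
#'
#' Returns the fiducial-sphere table in phantom coordinates: a central
#' 3 x 3 x 3 block of 27 spheres on a 40 mm cubic lattice, plus a cross of 5
#' spheres at each of the six outward faces (the face-centre grid point at
#' +/-80 mm and its four 40 mm neighbours in the face plane). All spheres
#' have 10.0 mm inner diameter. Numbering starts at plate 1 (+Y), increases
#' right to left (+X is left), then inferior to superior (+Z is superior),
#' which places the central sphere at index 29 and the origin.
#'
#' @return data.frame with columns id, x, y, z (mm), inner_diameter (mm),
#'   group (fiducial_internal or fiducial_face_{px,mx,py,my,pz,mz}).
#' @seealso [phantomLayout()], [groupFiducials()]
#' @export
buildFiducialLattice <- function() {
  a <- 40
  internal <- expand.grid(x = c(-a, 0, a), y = c(-a, 0, a), z = c(-a, 0, a))
  internal$group <- "fiducial_internal"
  faces <- list(
    px = c(1, 0, 0), mx = c(-1, 0, 0),
    py = c(0, 1, 0), my = c(0, -1, 0),
    pz = c(0, 0, 1), mz = c(0, 0, -1)
  )
  face_rows <- do.call(rbind, lapply(names(faces), function(nm) {
    n <- faces[[nm]]
    centre <- 2 * a * n
    perp <- which(n == 0)
    offs <- rbind(c(0, 0, 0))
    for (p in perp) {
      e <- c(0, 0, 0); e[p] <- a
      offs <- rbind(offs, e, -e)
    }
    pos <- sweep(offs, 2, centre, "+")
    data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
               group = paste0("fiducial_face_", nm))
  }))
  f <- rbind(internal[, c("x", "y", "z", "group")], face_rows)
  # plate 1 (+Y) first, then inferior->superior (z), then right->left (x)
  f <- f[order(-f$y, f$z, f$x), ]
  f$id <- seq_len(nrow(f))
  f$inner_diameter <- 10.0
  rownames(f) <- NULL
  f[, c("id", "x", "y", "z", "inner_diameter", "group")]
}

#' Group fiducial sphere ids by lattice group
#'
#' Partitions the 57 fiducial ids into the seven presentation groups: the 27
#' internal spheres and the six 5-sphere face groups.
#'
#' @param layout a [PhantomLayout-class] (or the fiducial data.frame).
#' @return named list mapping group name to integer ids.
#' @export
groupFiducials <- function(layout) {
  f <- if (is(layout, "PhantomLayout")) fiducials(layout) else layout
  split(f$id, f$group)
}

#' Build one MR parameter array
#'
#' Each array holds 14 spheres of 15 mm inner diameter: elements 1-10
#' equally spaced (36 degrees apart) on a 50 mm radius ring in the plate
#' (XZ) plane, starting at the superior (+Z) position and proceeding toward
#' +X (left); elements 11-14 on the interior 40 mm grid at (+/-20, +/-20).
#' Array planes: PD on plate 3, MnCl2 on plate 4, NiCl2 on plate 5, each
#' offset from the plate by the mounting distance.
#'
#' @param kind one of "NiCl2", "MnCl2", "PD".
#' @return data.frame with columns array, element, x, y, z (mm),
#'   inner_diameter (mm), ring ("outer"/"inner").
#' @export
buildParameterArray <- function(kind) {
  kind <- match.arg(kind, c("NiCl2", "MnCl2", "PD"))
  y0 <- switch(kind,
    PD = .plateY[["plate3"]] + .mountOffsetY,
    MnCl2 = .plateY[["plate4"]] + .mountOffsetY,
    NiCl2 = .plateY[["plate5"]] + .mountOffsetY
  )
  ang <- pi / 2 - (0:9) * 2 * pi / 10   # start at +Z, advance toward +X
  outer <- data.frame(
    element = 1:10,
    x = 50 * cos(ang), z = 50 * sin(ang), ring = "outer"
  )
  inner <- data.frame(
    element = 11:14,
    x = c(-20, 20, -20, 20), z = c(20, 20, -20, -20), ring = "inner"
  )
  out <- rbind(outer, inner)
  out$x[abs(out$x) < 1e-12] <- 0
  out$z[abs(out$z) < 1e-12] <- 0
  data.frame(array = kind, element = out$element,
             x = out$x, y = y0, z = out$z,
             inner_diameter = 15, ring = out$ring)
}

#' Build a resolution-inset hole set
#'
#' Each inset holds five hole sizes (coarse: 0.6-1.0 mm; fine: 0.4-0.8 mm in
#' 0.1 mm steps). Per size there is a 4 x 4 square array with
#' centre-to-centre pitch of twice the hole diameter, duplicated at a 10
#' degree angle sharing the corner hole nearest the inset origin: the
#' duplicate is the point-reflected grid through the shared hole rotated by
#' 10 degrees, so the pair shares exactly one hole and no two holes overlap.
#' That gives 31 holes per size and 155 per inset. Coordinates (u, v) are mm
#' in the inset plane relative to the inset origin.
#'
#' @param kind "coarse" or "fine".
#' @return data.frame with columns size_mm, hole, u, v, diameter_mm,
#'   group_angle_deg (0 or 10), gi, gj (grid indices 0-3 within the 4 x 4
#'   block), shared (logical).
#' @export
buildResolutionInset <- function(kind) {
  kind <- match.arg(kind, c("coarse", "fine"))
  sizes <- if (kind == "coarse") seq(0.6, 1.0, by = 0.1) else seq(0.4, 0.8, by = 0.1)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  u_cursor <- 0
  blocks <- lapply(sizes, function(d) {
    p <- 2 * d
    ij <- as.matrix(expand.grid(i = 0:3, j = 0:3))
    g <- ij * p
    rot <- t(R %*% t(-g))            # point-reflected grid, rotated 10 deg
    keep <- -1                       # (0,0) is the shared hole, keep once
    # place the shared hole so the whole block starts at the cursor
    umin <- min(c(g[, 1], rot[, 1]))
    u0 <- u_cursor - umin
    v0 <- -min(c(g[, 2], rot[, 2]))
    u_cursor <<- u_cursor + diff(range(c(g[, 1], rot[, 1]))) + d + 3
    df <- data.frame(
      size_mm = d,
      hole = seq_len(2 * nrow(g) - 1),
      u = c(g[, 1], rot[keep, 1]) + u0,
      v = c(g[, 2], rot[keep, 2]) + v0,
      diameter_mm = d,
      group_angle_deg = c(rep(0, nrow(g)), rep(10, nrow(g) - 1)),
      gi = c(ij[, 1], ij[keep, 1]),
      gj = c(ij[, 2], ij[keep, 2]),
      shared = c(TRUE, rep(FALSE, nrow(g) - 1), rep(FALSE, nrow(g) - 1))
    )
    df
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Build the slice-profile wedge specification
#'
#' Two 10-degree wedges of 10 mm height inside a rectangular prism, one with
#' positive and one with negative inclination, read out with 4 mm x 50 mm
#' rectangular ROIs. The 10 mm height bounds the maximum measurable slice
#' thickness.
#'
#' @return list with wedge_angle_deg, height_mm, roi_mm, orientations, and
#'   the two wedge-prism centres in phantom mm.
#' @export
buildWedgeSpec <- function() {
  list(
    wedge_angle_deg = 10,
    height_mm = 10,
    roi_mm = c(4, 50),
    orientations = c(1, -1),
    centers = rbind(pos = c(0, .plateY[["plate2"]] + .mountOffsetY, 5),
                    neg = c(0, .plateY[["plate2"]] + .mountOffsetY, -5))
  )
}

#' Construct the complete phantom layout
#'
#' Assembles the fiducial lattice, the three MR parameter arrays, both
#' resolution insets, and the wedge specification into a
#' [PhantomLayout-class] in phantom coordinates (mm; +X left, +Y posterior,
#' +Z superior; origin at the central fiducial sphere).
#'
#' @return a [PhantomLayout-class].
#' @export
phantomLayout <- function() {
  arrays <- rbind(buildParameterArray("NiCl2"),
                  buildParameterArray("MnCl2"),
                  buildParameterArray("PD"))
  new("PhantomLayout",
      fiducials = buildFiducialLattice(),
      arrays = arrays,
      insets = list(coarse = buildResolutionInset("coarse"),
                    fine = buildResolutionInset("fine")),
      wedges = buildWedgeSpec(),
      units = "mm",
      convention = "+X left, +Y posterior, +Z superior; origin at central fiducial")
}

#' Export / import a phantom layout as JSON
#'
#' The JSON carries explicit units and the coordinate convention and round
#' trips bit-exactly, so it can be replaced with coordinates taken from the
#' published 3D model files.
#'
#' @param layout a [PhantomLayout-class].
#' @param path file path to write to / read from.
#' @return `layoutToJSON` returns `path` invisibly; `layoutFromJSON` returns
#'   a [PhantomLayout-class].
#' @export
layoutToJSON <- function(layout, path) {
  obj <- list(
    units = layout@units,
    convention = layout@convention,
    fiducials = layout@fiducials,
    arrays = layout@arrays,
    insets = layout@insets,
    wedges = list(
      wedge_angle_deg = layout@wedges$wedge_angle_deg,
      height_mm = layout@wedges$height_mm,
      roi_mm = layout@wedges$roi_mm,
      orientations = layout@wedges$orientations,
      centers = as.data.frame(layout@wedges$centers)
    )
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname layoutToJSON
#' @export
layoutFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON does not distinguish 10 from 10L: restore the canonical column
  # types so the round trip is bit-exact
  setTypes <- function(df, int_cols, dbl_cols, lgl_cols = character(0)) {
    for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
    for (cc in intersect(dbl_cols, names(df))) df[[cc]] <- as.numeric(df[[cc]])
    for (cc in intersect(lgl_cols, names(df))) df[[cc]] <- as.logical(df[[cc]])
    df
  }
  fid <- setTypes(as.data.frame(obj$fiducials), "id",
                  c("x", "y", "z", "inner_diameter"))
  arr <- setTypes(as.data.frame(obj$arrays), "element",
                  c("x", "y", "z", "inner_diameter"))
  insets <- lapply(obj$insets, function(h)
    setTypes(as.data.frame(h), c("hole", "gi", "gj"),
             c("size_mm", "u", "v", "diameter_mm", "group_angle_deg"),
             "shared"))
  wc <- matrix(as.numeric(as.matrix(obj$wedges$centers)), ncol = 3)
  rownames(wc) <- c("pos", "neg")
  new("PhantomLayout",
      fiducials = fid,
      arrays = arr,
      insets = insets,
      wedges = list(
        wedge_angle_deg = as.numeric(obj$wedges$wedge_angle_deg),
        height_mm = as.numeric(obj$wedges$height_mm),
        roi_mm = as.numeric(obj$wedges$roi_mm),
        orientations = as.numeric(obj$wedges$orientations),
        centers = wc
      ),
      units = obj$units,
      convention = obj$convention)
}
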