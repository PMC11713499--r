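#' Construct a ScalarVolume
#'
#' @param values numeric 3D array (HU for CT, Gy for dose).
#' @param spacing numeric(3), per-axis voxel size in mm.
#' @param origin numeric(3), world position (mm) of the center of voxel
#'   (0,0,0).
#' @param unit `"HU"`, `"Gy"` or `""`.
#' @return A [ScalarVolume-class].
#' @examples
#' v <- ScalarVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' spacing(v)
#' @export
ScalarVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         unit = "") {
  storage.mode(values) <- "double"
  new("ScalarVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit)
}

#' Construct a VectorField
#'
#' @param displacements numeric 4D array `c(nx, ny, nz, 3)` of mm
#'   displacements on the reference grid.
#' @param spacing,origin grid geometry of the reference grid.
#' @return A [VectorField-class].
#' @export
VectorField <- function(displacements, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  storage.mode(displacements) <- "double"
  new("VectorField", displacements = displacements,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @param name structure label.
#' @param values logical 3D array.
#' @param spacing,origin grid geometry, matching the companion volume.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(name, values, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  mode(values) <- "logical"
  new("BinaryMask", name = name, values = values,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Grid compatibility of two volumes
#'
#' Two objects are grid-compatible when their array dimensions match and
#' spacing and origin agree within 1e-6 mm, the tolerance that absorbs
#' text round-tripping of geometry headers.
#'
#' @param a,b [ScalarVolume-class], [BinaryMask-class] or
#'   [VectorField-class] objects.
#' @return logical scalar.
#' @export
gridCompatible <- function(a, b) {
  da <- .gridDim(a); db <- .gridDim(b)
  all(da == db) &&
    all(abs(spacing(a) - spacing(b)) <= .EPS_GRID) &&
    all(abs(origin(a) - origin(b)) <= .EPS_GRID)
}

.gridDim <- function(x) {
  if (is(x, "VectorField")) dim(x@displacements)[1:3] else dim(x@values)
}

.stopIfIncompatible <- function(a, b, what = "inputs") {
  if (!gridCompatible(a, b))
    stop(what, " are not grid-compatible (dimensions/spacing/origin differ)")
  invisible(TRUE)
}

.asPointMatrix <- function(point) {
  if (is.matrix(point)) {
    if (ncol(point) != 3L) stop("'point' matrix must have 3 columns")
    point
  } else {
    if (length(point) != 3L) stop("'point' must have 3 components")
    matrix(point, 1L, 3L)
  }
}

#' World/index coordinate mapping
#'
#' `worldToIndex` maps world coordinates (mm) to continuous 0-based voxel
#' indices; `indexToWorld` is its inverse. Indices may be fractional and may
#' fall outside the grid; callers decide how to treat out-of-bounds values.
#'
#' @param volume a [ScalarVolume-class] (or any gridded object).
#' @param point numeric(3) or an n x 3 matrix of world points (mm) /
#'   continuous indices.
#' @return numeric(3) or n x 3 matrix of continuous indices / world points.
#' @examples
#' v <- ScalarVolume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
#' worldToIndex(v, c(4, 0, 0))   # (2, 0, 0)
#' indexToWorld(v, c(2, 0, 0))   # (4, 0, 0)
#' @export
worldToIndex <- function(volume, point) {
  p <- .asPointMatrix(point)
  idx <- sweep(sweep(p, 2L, origin(volume), "-"), 2L, spacing(volume), "/")
  if (is.matrix(point)) idx else idx[1L, ]
}

#' @rdname worldToIndex
#' @export
indexToWorld <- function(volume, point) {
  p <- .asPointMatrix(point)
  w <- sweep(sweep(p, 2L, spacing(volume), "*"), 2L, origin(volume), "+")
  if (is.matrix(point)) w else w[1L, ]
}

#' Trilinear interpolation of a ScalarVolume at world points
#'
#' Exact at voxel centers; linear in between. The volume's physical extent
#' is the voxel-center bounding box `[origin, origin + (dim - 1) * spacing]`.
#'
#' @param volume a [ScalarVolume-class].
#' @param point numeric(3) or n x 3 matrix of world points, mm.
#' @param outside `"error"` to signal on out-of-extent points, `"fill"` to
#'   substitute `fill`.
#' @param fill value returned for out-of-extent points when
#'   `outside = "fill"`.
#' @return numeric vector of interpolated values, one per point.
#' @examples
#' v <- ScalarVolume(array(rep(3 * (0:7), 64), c(8, 8, 8)))  # v(x) = 3x
#' interpolateAt(v, c(1.25, 4, 4))  # 3.75
#' @export
interpolateAt <- function(volume, point, outside = c("error", "fill"),
                          fill = NA_real_) {
  outside <- match.arg(outside)
  pts <- .asPointMatrix(point)
  idx <- worldToIndex(volume, pts)
  d <- dim(volume@values)
  tol <- 1e-9
  ok <- idx[, 1] >= -tol & idx[, 1] <= d[1] - 1 + tol &
        idx[, 2] >= -tol & idx[, 2] <= d[2] - 1 + tol &
        idx[, 3] >= -tol & idx[, 3] <= d[3] - 1 + tol
  if (outside == "error" && !all(ok))
    stop("point outside volume extent")
  out <- rep(fill, nrow(pts))
  if (any(ok))
    out[ok] <- .trilinear(volume@values, idx[ok, , drop = FALSE])
  out
}

# idx: matrix of 0-based continuous indices, already inside the extent
.trilinear <- function(arr, idx) {
  d <- dim(arr)
  i0 <- floor(idx)
  for (k in 1:3) i0[, k] <- pmin(pmax(i0[, k], 0), d[k] - 2)
  # degenerate axes (single-voxel dimension)
  for (k in 1:3) if (d[k] == 1L) i0[, k] <- 0
  f <- idx - i0
  for (k in 1:3) f[, k] <- pmin(pmax(f[, k], 0), 1)
  g <- function(dx, dy, dz) {
    ii <- cbind(pmin(i0[, 1] + dx, d[1] - 1) + 1,
                pmin(i0[, 2] + dy, d[2] - 1) + 1,
                pmin(i0[, 3] + dz, d[3] - 1) + 1)
    arr[ii]
  }
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 1, 0) * fx * fy * (1 - fz) +
    g(1, 0, 1) * fx * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy * fz +
    g(1, 1, 1) * fx * fy * fz
}

# world coordinates of all voxel centers of a gridded object, as n x 3 matrix
.gridPoints <- function(x) {
  d <- .gridDim(x)
  sp <- spacing(x); o <- origin(x)
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Resample a volume onto a reference grid
#'
#' Every output voxel takes the trilinearly interpolated value of `moving`
#' at the reference voxel's world position plus the local displacement
#' (pull/backward warping). Values below `floorValue` are clamped to
#' `floorValue`, and samples falling outside the moving volume's extent are
#' filled with `floorValue` (air for CT, zero for dose).
#'
#' @param moving the [ScalarVolume-class] to resample.
#' @param reference the [ScalarVolume-class] defining the output grid.
#' @param dvf optional [VectorField-class] on the reference grid; `NULL`
#'   means the identity transform.
#' @param floorValue lower clamp and out-of-extent fill; `-1000` HU for CT,
#'   use `0` for dose grids.
#' @return A [ScalarVolume-class] on the reference grid.
#' @export
resampleToReference <- function(moving, reference, dvf = NULL,
                                floorValue = -1000) {
  stopifnot(is(moving, "ScalarVolume"), is(reference, "ScalarVolume"))
  pts <- .gridPoints(reference)
  if (!is.null(dvf)) {
    if (!gridCompatible(dvf, reference))
      stop("displacement field is not defined on the reference grid")
    disp <- matrix(dvf@displacements, ncol = 3L)
    pts <- pts + disp
  }
  vals <- interpolateAt(moving, pts, outside = "fill", fill = floorValue)
  vals[vals < floorValue] <- floorValue
  ScalarVolume(array(vals, dim(reference@values)),
               spacing = spacing(reference), origin = origin(reference),
               unit = moving@unit)
}
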