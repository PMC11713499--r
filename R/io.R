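#' Read and write volumes as NIfTI
#'
#' `writeScalarVolume`/`readScalarVolume` round-trip a
#' [ScalarVolume-class] through `.nii`/`.nii.gz`, `writeBinaryMask`/
#' `readBinaryMask` a [BinaryMask-class] (stored as 0/1), and
#' `writeVectorField`/`readVectorField` a [VectorField-class] (stored as a
#' 4D image). The geometry is carried in the NIfTI affine; only
#' axis-aligned orientations are supported (per-axis flips are normalized
#' to positive spacing at load time, oblique/permuted affines are
#' rejected).
#'
#' @param x the object to write.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param unit unit label to attach on read (`"HU"`, `"Gy"` or `""`).
#' @param name structure label to attach to a mask on read.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name nifti-io
NULL

.affineFor <- function(spacing, origin) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing)
  A[1:3, 4] <- origin
  A
}

.writeNifti <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
  RNifti::sform(img) <- structure(.affineFor(spacing, origin), code = 2L)
  RNifti::qform(img) <- structure(.affineFor(spacing, origin), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.readNifti <- function(path) {
  img <- RNifti::readNifti(path)
  A <- RNifti::xform(img)
  M <- A[1:3, 1:3]
  if (any(abs(M[row(M) != col(M)]) > 1e-4 * max(abs(diag(M)))))
    stop("oblique or permuted NIfTI orientation is not supported")
  arr <- array(as.numeric(img), dim(img))  # strip the niftiImage class
  dm <- dim(arr)
  sp <- abs(diag(M))
  org <- A[1:3, 4]
  for (k in 1:3) {
    if (diag(M)[k] < 0) {  # flip to positive-spacing convention
      idx <- lapply(seq_along(dm), function(j) seq_len(dm[j]))
      idx[[k]] <- rev(idx[[k]])
      arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      org[k] <- org[k] - sp[k] * (dm[k] - 1)
    }
  }
  list(arr = arr, spacing = sp, origin = org)
}

#' @rdname nifti-io
#' @export
writeScalarVolume <- function(x, path) {
  stopifnot(is(x, "ScalarVolume"))
  .writeNifti(values(x), spacing(x), origin(x), path)
}

#' @rdname nifti-io
#' @export
readScalarVolume <- function(path, unit = "") {
  r <- .readNifti(path)
  if (length(dim(r$arr)) != 3L) stop("expected a 3D image")
  ScalarVolume(r$arr, spacing = r$spacing, origin = r$origin, unit = unit)
}

#' @rdname nifti-io
#' @export
writeBinaryMask <- function(x, path) {
  stopifnot(is(x, "BinaryMask"))
  .writeNifti(array(as.integer(values(x)), dim(values(x))), spacing(x),
              origin(x), path)
}

#' @rdname nifti-io
#' @export
readBinaryMask <- function(path, name = "mask") {
  r <- .readNifti(path)
  if (length(dim(r$arr)) != 3L) stop("expected a 3D image")
  BinaryMask(name, r$arr != 0, spacing = r$spacing, origin = r$origin)
}

#' @rdname nifti-io
#' @export
writeVectorField <- function(x, path) {
  stopifnot(is(x, "VectorField"))
  .writeNifti(x@displacements, spacing(x), origin(x), path)
}

#' @rdname nifti-io
#' @export
readVectorField <- function(path) {
  r <- .readNifti(path)
  if (length(dim(r$arr)) != 4L || dim(r$arr)[4] != 3L)
    stop("expected a 4D image with 3 components")
  VectorField(r$arr, spacing = r$spacing, origin = r$origin)
}

#' Read and write a CaseBundle as a directory of NIfTI files
#'
#' A case directory holds `planning_ct.nii.gz`, `synthetic_ct.nii.gz`,
#' `dose_reference.nii.gz`, `dose_evaluated.nii.gz`, one
#' `mask_<NAME>.nii.gz` per structure, and `meta.json` with the
#' prescription metadata.
#'
#' @param bundle a [CaseBundle-class].
#' @param dir directory path (created if missing).
#' @return `writeCaseBundle` returns `dir` invisibly; `readCaseBundle`
#'   the reconstructed [CaseBundle-class].
#' @export
writeCaseBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeScalarVolume(bundle@planningCT, file.path(dir, "planning_ct.nii.gz"))
  writeScalarVolume(bundle@syntheticCT,
                    file.path(dir, "synthetic_ct.nii.gz"))
  writeScalarVolume(bundle@doseReference,
                    file.path(dir, "dose_reference.nii.gz"))
  writeScalarVolume(bundle@doseEvaluated,
                    file.path(dir, "dose_evaluated.nii.gz"))
  for (nm in names(bundle@structures))
    writeBinaryMask(bundle@structures[[nm]],
                    file.path(dir, paste0("mask_", nm, ".nii.gz")))
  jsonlite::write_json(
    list(prescriptionDose = bundle@prescriptionDose,
         prescriptionIsodoseFraction = bundle@prescriptionIsodoseFraction),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCaseBundle
#' @export
readCaseBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  maskFiles <- list.files(dir, pattern = "^mask_.*\\.nii(\\.gz)?$")
  structures <- list()
  for (f in maskFiles) {
    nm <- sub("^mask_", "", sub("\\.nii(\\.gz)?$", "", f))
    structures[[nm]] <- readBinaryMask(file.path(dir, f), name = nm)
  }
  new("CaseBundle",
      planningCT = readScalarVolume(file.path(dir, "planning_ct.nii.gz"),
                                    unit = "HU"),
      syntheticCT = readScalarVolume(file.path(dir, "synthetic_ct.nii.gz"),
                                     unit = "HU"),
      doseReference = readScalarVolume(
        file.path(dir, "dose_reference.nii.gz"), unit = "Gy"),
      doseEvaluated = readScalarVolume(
        file.path(dir, "dose_evaluated.nii.gz"), unit = "Gy"),
      structures = structures,
      prescriptionDose = meta$prescriptionDose,
      prescriptionIsodoseFraction = meta$prescriptionIsodoseFraction)
}

#' Rasterize planar contours to a binary mask
#'
#' Converts a structure described by closed planar polygons (one or more
#' per axial slice, world-mm vertices) into a [BinaryMask-class] on a
#' reference grid using even-odd polygon filling per slice: a voxel center
#' is inside when a ray from it crosses the slice's polygon edges an odd
#' number of times, so overlapping polygons create holes. This is the
#' geometry underlying DICOM-RT structure-set rasterization; the contours
#' themselves can come from any source (e.g. a plain-text export).
#'
#' @param contours list of `list(z =, x =, y =)` items: `z` the world z of
#'   the contour plane, `x`/`y` equal-length vertex coordinate vectors of
#'   one closed polygon (not repeated at the end).
#' @param reference a [ScalarVolume-class] defining the output grid.
#' @param name structure label.
#' @return A [BinaryMask-class] on the reference grid.
#' @export
rasterizeContours <- function(contours, reference, name = "structure") {
  d <- dim(values(reference))
  sp <- spacing(reference); org <- origin(reference)
  out <- array(FALSE, d)
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  px <- rep(xs, times = d[2])
  py <- rep(ys, each = d[1])
  for (ct in contours) {
    stopifnot(length(ct$x) == length(ct$y), length(ct$x) >= 3L)
    k <- round((ct$z - org[3]) / sp[3]) + 1L
    if (k < 1L || k > d[3]) next  # contour plane outside the grid
    inside <- rep(FALSE, length(px))
    n <- length(ct$x)
    j <- n
    for (i in seq_len(n)) {
      xi <- ct$x[i]; yi <- ct$y[i]; xj <- ct$x[j]; yj <- ct$y[j]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    out[, , k] <- xor(out[, , k], matrix(inside, d[1], d[2]))
  }
  BinaryMask(name, out, spacing = sp, origin = org)
}
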