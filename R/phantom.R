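#' Digital head-phantom specification
#'
#' Defines the geometry and tissue HU of the synthetic head used to stand in
#' for patient planning CTs: an ellipsoidal soft-tissue head wrapped in a
#' skull shell of constant thickness, over an air background, with optional
#' sinus-like air cavities in the anterior soft tissue.
#'
#' Defaults give a 32^3 grid at 6 mm spacing (a coarse but fully featured
#' head: ~19 cm x 15 cm x 17 cm) with soft tissue at 30 HU, bone at 1000 HU
#' and air at -1000 HU, matching the tissue classes a brain synthetic-CT
#' algorithm must reproduce.
#'
#' @param gridShape integer(3) voxel counts.
#' @param spacing numeric(3) mm.
#' @param headRadii numeric(3) outer ellipsoid semi-axes, mm.
#' @param skullThickness shell thickness, mm.
#' @param airCavityRadii radii (mm) of sinus-like air spheres; `numeric(0)`
#'   for none.
#' @param huSoft,huBone,huAir tissue HU.
#' @param seed integer seed for any stochastic anatomy detail (cavity
#'   placement jitter).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 32L), spacing = c(6, 6, 6),
                        headRadii = c(95, 75, 85), skullThickness = 8,
                        airCavityRadii = c(12, 9), huSoft = 30,
                        huBone = 1000, huAir = -1000, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), headRadii = as.numeric(headRadii),
      skullThickness = as.numeric(skullThickness),
      airCavityRadii = as.numeric(airCavityRadii), huSoft = huSoft,
      huBone = huBone, huAir = huAir, seed = as.integer(seed))
}

#' Synthetic-CT conversion-error model
#'
#' @param globalBias HU added uniformly inside BODY (synthetic CTs tend to
#'   read high; ~20-30 HU emulates reported head cohorts).
#' @param noiseSigma SD of zero-mean Gaussian voxel noise inside BODY, HU.
#' @param boneDilation signed mm; > 0 misclassifies peri-osseous soft tissue
#'   as bone (dilation), < 0 erodes the bone compartment.
#' @param contourShift body-surface displacement, mm (voxel-quantized).
#' @param contourAxis axis (1..3) of the contour shift.
#' @param metalArtifact `c(cx, cy, cz, radius, huVoid)` world-mm sphere set
#'   to `huVoid` (susceptibility signal void), or `NULL`.
#' @return An [ErrorModel-class].
#' @export
errorModel <- function(globalBias = 0, noiseSigma = 0, boneDilation = 0,
                       contourShift = 0, contourAxis = 1L,
                       metalArtifact = NULL) {
  new("ErrorModel", globalBias = globalBias, noiseSigma = noiseSigma,
      boneDilation = boneDilation, contourShift = contourShift,
      contourAxis = as.integer(contourAxis),
      metalArtifact = if (is.null(metalArtifact)) numeric(0)
                      else as.numeric(metalArtifact))
}

#' Toy parallel-beam specification
#'
#' @param direction ray direction, `"x+"`, `"x-"`, `"y+"`, `"y-"`, `"z+"`
#'   or `"z-"`.
#' @param entranceDose dose at the body surface, Gy.
#' @param attenuationScale effective attenuation per mm at water density.
#' @param targetCenter world mm of the spherical target.
#' @param targetRadius target radius, mm.
#' @return A [BeamSpec-class].
#' @export
beamSpec <- function(direction = "x+", entranceDose = 60,
                     attenuationScale = 0.004, targetCenter = c(0, 0, 0),
                     targetRadius = 15) {
  new("BeamSpec", direction = direction, entranceDose = entranceDose,
      attenuationScale = attenuationScale,
      targetCenter = as.numeric(targetCenter),
      targetRadius = as.numeric(targetRadius))
}

# centered grid: world (0,0,0) at the grid center
.phantomOrigin <- function(shape, spacing) -(shape - 1) / 2 * spacing

.sphereMask <- function(shape, spacing, org, center, radius) {
  xs <- org[1] + (seq_len(shape[1]) - 1) * spacing[1] - center[1]
  ys <- org[2] + (seq_len(shape[2]) - 1) * spacing[2] - center[2]
  zs <- org[3] + (seq_len(shape[3]) - 1) * spacing[3] - center[3]
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  array(r2 <= radius^2, shape)
}

#' Build the phantom anatomy
#'
#' Deterministically constructs a planning-CT-like [ScalarVolume-class]
#' (background air, soft-tissue ellipsoid, skull shell, embedded air
#' cavities) and its structure set: `BODY` (all voxels above
#' `huAir + 50`), a spherical `PTV`, and organ-at-risk spheres.
#'
#' @param spec a [PhantomSpec-class].
#' @param targetCenter world mm of the PTV sphere (must lie inside BODY).
#' @param targetRadius PTV radius, mm.
#' @param oars named list of `list(center =, radius =)` OAR spheres in world
#'   mm; the defaults place a brainstem-like sphere inferiorly-posteriorly
#'   and a small lens-like sphere anteriorly.
#' @return `list(ct = ScalarVolume, structures = named list of BinaryMask)`.
#' @export
buildAnatomy <- function(spec, targetCenter = c(0, 0, 0), targetRadius = 15,
                         oars = NULL) {
  shape <- spec@gridShape; sp <- spec@spacing
  org <- .phantomOrigin(shape, sp)
  a <- spec@headRadii; t <- spec@skullThickness
  xs <- (org[1] + (seq_len(shape[1]) - 1) * sp[1])
  ys <- (org[2] + (seq_len(shape[2]) - 1) * sp[2])
  zs <- (org[3] + (seq_len(shape[3]) - 1) * sp[3])
  eOut <- outer(outer((xs / a[1])^2, (ys / a[2])^2, "+"), (zs / a[3])^2, "+")
  eIn  <- outer(outer((xs / (a[1] - t))^2, (ys / (a[2] - t))^2, "+"),
                (zs / (a[3] - t))^2, "+")
  vals <- array(spec@huAir, shape)
  vals[eOut <= 1] <- spec@huBone   # shell ...
  vals[eIn <= 1] <- spec@huSoft    # ... hollowed by the inner ellipsoid
  # sinus-like air cavities in the anterior soft tissue, jittered by seed
  if (length(spec@airCavityRadii)) {
    set.seed(spec@seed)
    inner <- a - t
    for (i in seq_along(spec@airCavityRadii)) {
      r <- spec@airCavityRadii[i]
      side <- if (i %% 2L == 0L) -1 else 1
      ctr <- c(side * 0.25 * inner[1], -0.45 * inner[2], -0.25 * inner[3]) +
        rnorm(3, 0, 1.5)
      cav <- .sphereMask(shape, sp, org, ctr, r) & eIn <= 1
      vals[cav] <- spec@huAir
    }
  }
  ct <- ScalarVolume(vals, spacing = sp, origin = org, unit = "HU")
  body <- BinaryMask("BODY", vals > spec@huAir + 50, sp, org)
  ptv <- .sphereMask(shape, sp, org, targetCenter, targetRadius)
  if (!any(ptv) || any(ptv & !body@values))
    stop("target sphere lies (partly) outside the body")
  if (is.null(oars)) {
    inner <- a - t
    oars <- list(
      brainstem = list(center = c(0, 0.35 * inner[2], -0.35 * inner[3]),
                       radius = 10),
      lens = list(center = c(0.22 * inner[1], -0.75 * inner[2], 0.1 * inner[3]),
                  radius = 6))
  }
  structures <- c(
    list(BODY = body,
         PTV = BinaryMask("PTV", ptv, sp, org)),
    lapply(setNames(seq_along(oars), names(oars)), function(i) {
      m <- .sphereMask(shape, sp, org, oars[[i]]$center, oars[[i]]$radius)
      BinaryMask(names(oars)[i], m & body@values, sp, org)
    }))
  list(ct = ct, structures = structures)
}

# shift a 3D array by n voxels along axis, filling with `fill`
.shiftArray <- function(arr, n, axis, fill) {
  if (n == 0L) return(arr)
  d <- dim(arr)
  out <- array(fill, d)
  idxSrc <- idxDst <- lapply(d, seq_len)
  if (n > 0) {
    idxDst[[axis]] <- (n + 1):d[axis]; idxSrc[[axis]] <- 1:(d[axis] - n)
  } else {
    idxDst[[axis]] <- 1:(d[axis] + n); idxSrc[[axis]] <- (1 - n):d[axis]
  }
  if (length(idxDst[[axis]]) > 0)
    out[idxDst[[1]], idxDst[[2]], idxDst[[3]]] <-
      arr[idxSrc[[1]], idxSrc[[2]], idxSrc[[3]]]
  out
}

# binary dilation with a spherical structuring element of radius r mm
.binaryDilate <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  nmax <- floor(r / spacing)
  out <- mask
  for (dx in -nmax[1]:nmax[1]) for (dy in -nmax[2]:nmax[2])
    for (dz in -nmax[3]:nmax[3]) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (sum((c(dx, dy, dz) * spacing)^2) > r^2) next
      sh <- .shiftArray(mask, dx, 1L, FALSE)
      if (dy != 0) sh <- .shiftArray(sh, dy, 2L, FALSE)
      if (dz != 0) sh <- .shiftArray(sh, dz, 3L, FALSE)
      out <- out | sh
    }
  out
}

.binaryErode <- function(mask, r, spacing) !.binaryDilate(!mask, r, spacing)

#' Apply the conversion-error model to a planning CT
#'
#' Produces the synthetic-CT member of a pair by perturbing the planning CT
#' inside the BODY mask: bone-compartment morphology first (on the clean
#' HU), then the global bias, Gaussian noise, the voxel-quantized body
#' contour shift, and finally the metal-artifact void. Voxels outside BODY
#' are untouched except where the contour shift moves the surface itself.
#'
#' @param ct planning-CT [ScalarVolume-class].
#' @param body BODY [BinaryMask-class] on the same grid.
#' @param model an [ErrorModel-class].
#' @param seed integer seed for the noise draw.
#' @param boneThreshold HU above which a voxel belongs to the bone
#'   compartment for the morphology operation.
#' @return A synthetic-CT [ScalarVolume-class].
#' @export
applyErrorModel <- function(ct, body, model, seed = 1L, boneThreshold = 200) {
  .stopIfIncompatible(ct, body, "ct and body mask")
  vals <- values(ct)
  inside <- values(body)
  if (!any(inside)) stop("degenerate body contour: BODY mask is empty")
  sp <- spacing(ct)
  # representative tissue values for morphological reassignment
  bone <- vals > boneThreshold & inside
  huBoneRep <- if (any(bone)) mean(vals[bone]) else boneThreshold
  softSel <- inside & !bone
  huSoftRep <- if (any(softSel)) median(vals[softSel]) else 0
  huAirRep <- min(vals)
  if (model@boneDilation > 0 && any(bone)) {
    grown <- .binaryDilate(bone, model@boneDilation, sp)
    vals[grown & !bone & inside] <- huBoneRep
  } else if (model@boneDilation < 0 && any(bone)) {
    shrunk <- .binaryErode(bone, -model@boneDilation, sp)
    vals[bone & !shrunk] <- huSoftRep
  }
  if (model@globalBias != 0) vals[inside] <- vals[inside] + model@globalBias
  if (model@noiseSigma > 0) {
    set.seed(as.integer(seed))
    vals[inside] <- vals[inside] + rnorm(sum(inside), 0, model@noiseSigma)
  }
  if (model@contourShift != 0) {
    ax <- model@contourAxis
    n <- round(model@contourShift / sp[ax])
    if (n != 0) {
      shifted <- .shiftArray(inside, n, ax, FALSE)
      vals[shifted & !inside] <- huSoftRep + model@globalBias
      vals[inside & !shifted] <- huAirRep
    }
  }
  if (length(model@metalArtifact) == 5L) {
    ma <- model@metalArtifact
    void <- .sphereMask(dim(vals), sp, origin(ct), ma[1:3], ma[4])
    vals[void & inside] <- ma[5]
  }
  ScalarVolume(vals, spacing = sp, origin = origin(ct), unit = "HU")
}

#' Toy depth-attenuation dose engine
#'
#' An explicitly simplified stand-in for a clinical dose algorithm: a
#' parallel beam travels along one axis and each ray deposits
#' `entranceDose * exp(-attenuationScale * radiologicalDepth)` at every
#' body voxel, where radiological depth integrates relative density
#' `rho(HU) = max(0, 1 + HU/1000)` from the body surface to the voxel
#' center. Dose is zero outside the body. The engine preserves the one
#' property the QA pipeline must detect: HU errors along the beam path
#' perturb the delivered dose.
#'
#' @param ct a CT [ScalarVolume-class].
#' @param beam a [BeamSpec-class] (axis-aligned direction).
#' @param bodyThreshold HU above which a voxel counts as body for the depth
#'   integration (default just above air).
#' @return A dose [ScalarVolume-class] in Gy.
#' @export
computeToyDose <- function(ct, beam, bodyThreshold = -950) {
  vals <- values(ct)
  axis <- match(substr(beam@direction, 1, 1), c("x", "y", "z"))
  forward <- substr(beam@direction, 2, 2) == "+"
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vals, perm)
  d <- dim(v)
  if (!forward) v <- v[d[1]:1, , , drop = FALSE]
  m <- matrix(v, nrow = d[1])
  bodym <- m > bodyThreshold
  entered <- apply(bodym, 2L, cummax) > 0
  rho <- pmax(0, 1 + m / 1000) * entered
  delta <- spacing(ct)[axis]
  cum <- apply(rho, 2L, cumsum)
  depth <- delta * (cum - rho / 2)
  dose <- beam@entranceDose * exp(-beam@attenuationScale * depth)
  dose[!(bodym & entered)] <- 0
  out <- array(dose, d)
  if (!forward) out <- out[d[1]:1, , , drop = FALSE]
  out <- aperm(out, order(perm))
  ScalarVolume(out, spacing = spacing(ct), origin = origin(ct), unit = "Gy")
}

#' Generate a complete synthetic validation case
#'
#' Builds the phantom anatomy, derives the synthetic CT through the error
#' model, computes the toy dose on both CTs, and bundles everything with
#' prescription metadata. Fully deterministic given the spec seed.
#'
#' The prescription dose is set to 95% of the mean reference dose inside
#' the PTV (so the target is covered at realistic V93/V100 levels), at the
#' 100% isodose level.
#'
#' @param spec a [PhantomSpec-class].
#' @param model an [ErrorModel-class].
#' @param beam a [BeamSpec-class]; its target defines the PTV sphere.
#' @return A [CaseBundle-class].
#' @examples
#' cb <- generateCase(phantomSpec(seed = 7), errorModel(globalBias = 25),
#'                    beamSpec())
#' cb
#' @export
generateCase <- function(spec, model = errorModel(), beam = beamSpec()) {
  anat <- buildAnatomy(spec, targetCenter = beam@targetCenter,
                       targetRadius = beam@targetRadius)
  pct <- anat$ct
  sct <- applyErrorModel(pct, anat$structures$BODY, model,
                         seed = spec@seed + 1L)
  doseRef <- computeToyDose(pct, beam)
  doseEval <- computeToyDose(sct, beam)
  ptv <- anat$structures$PTV
  presc <- 0.95 * mean(values(doseRef)[values(ptv)])
  new("CaseBundle", planningCT = pct, syntheticCT = sct,
      doseReference = doseRef, doseEvaluated = doseEval,
      structures = anat$structures, prescriptionDose = presc,
      prescriptionIsodoseFraction = 1)
}
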