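#' Construct a phantom specification
#'
#' Defaults emulate the study's acquisition: 0.5 mm in-plane pixels, 2.5 mm
#' axial spacing (5 mm slices reconstructed with 2.5 mm steps), an airway
#' spanning the nasopharyngeal dome to the upper hyoid across 44 axial
#' slices (about 11 cm), air at gray value 40 inside soft tissue at 200 on
#' the 0..255 scale (air/soft-tissue contrast is large on CT), and Gaussian
#' noise at 5\% of that contrast. Each region's lumen is a cylinder with a
#' mild (10\%) sinusoidal waist, so the narrowest cross-section — the
#' quantity the collapse statistic is built from — sits mid-region rather
#' than at a region boundary; radii are blended linearly over the two
#' slices straddling each landmark.
#'
#' @param shape Array dimensions \code{(nx, ny, nz)}.
#' @param spacing Voxel spacing mm; axial default 2.5 mm.
#' @param landmarks An [AirwayLandmarks-class]; the lumen spans
#'   \code{[zDome, zHyoidUpper)}.
#' @param expiratoryRadii Named per-region lumen radii (mm) at deep
#'   end-expiration; defaults 9 mm nasopharyngeal, 8 mm elsewhere.
#' @param radii Optional full 4x4 region-by-phase radius matrix overriding
#'   \code{expiratoryRadii} (which then only seeds unspecified phases).
#' @param tissueIntensity,airIntensity Gray values (tissue bright, air dark).
#' @param noiseSD Additive Gaussian noise SD in gray values.
#' @param wobbleAmplitude,wobbleCycles Sinusoidal centerline wobble (mm,
#'   cycles over the axial extent).
#' @param waist Fractional narrowing at each region's midpoint.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(64L, 64L, 44L),
                        spacing = c(0.5, 0.5, 2.5),
                        landmarks = airwayLandmarks(3, 12, 21, 30, 39),
                        expiratoryRadii = c(nasopharyngeal = 9,
                                            posterior_palatal = 8,
                                            retrolingual = 8,
                                            laryngopharyngeal = 8),
                        radii = NULL,
                        tissueIntensity = 200, airIntensity = 40,
                        noiseSD = 8, wobbleAmplitude = 1, wobbleCycles = 1,
                        waist = 0.1, seed = 1L) {
  if (is.null(radii)) {
    r <- unname(expiratoryRadii[.airwayRegions])
    radii <- matrix(rep(r, 4), nrow = 4,
                    dimnames = list(.airwayRegions, .airwayPhases))
  }
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      landmarks = landmarks, radii = radii,
      tissueIntensity = tissueIntensity, airIntensity = airIntensity,
      noiseSD = noiseSD, wobbleAmplitude = wobbleAmplitude,
      wobbleCycles = wobbleCycles, waist = waist, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ (%g, %g, %g) mm, noise SD %g\n",
              paste(object@shape, collapse = " x "),
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@noiseSD))
  cat("  expiratory radii (mm):",
      paste(sprintf("%s=%g", rownames(object@radii),
                    object@radii[, "deep_end_expiration"]), collapse = ", "),
      "\n")
})

## Analytic lumen radius per axial slice for one phase (NA outside the
## airway span). Waist places the narrowest section mid-region; radii are
## blended over the two slices straddling each interior landmark.
.radiusProfile <- function(spec, phase) {
  nz <- spec@shape[3]
  ranges <- partitionRegions(spec@landmarks)
  prof <- rep(NA_real_, nz)
  for (rg in names(ranges)) {
    s <- ranges[[rg]][["start"]]; e <- ranges[[rg]][["end"]]
    zs <- seq.int(s, e - 1L)
    u <- (zs - s + 0.5) / (e - s)
    prof[zs] <- spec@radii[rg, phase] * (1 - spec@waist * sin(pi * u)^2)
  }
  z <- unname(landmarkVector(spec@landmarks))
  for (zb in z[2:4]) {   # interior boundaries
    a <- prof[zb - 1L]; b <- prof[zb]
    prof[zb - 1L] <- (2 * a + b) / 3
    prof[zb]      <- (a + 2 * b) / 3
  }
  prof
}

#' Generate a synthetic airway CT volume
#'
#' Builds one respiratory-phase volume of the phantom described by a
#' [PhantomSpec-class]: a dark tubular air column (per-region caliber for
#' the requested phase, optional sinusoidal centerline wobble) inside
#' bright soft tissue, with additive Gaussian noise. The result carries a
#' \code{"groundTruth"} attribute with the landmarks and the analytic
#' per-slice lumen radius and area, retrievable with [groundTruth()].
#' Fully deterministic given the spec (including its seed) and phase.
#'
#' @param spec A [PhantomSpec-class].
#' @param phase One of [airwayPhases()].
#' @param subjectID Identifier stored on the volume.
#' @return A [CTVolume-class].
#' @examples
#' vol <- generatePhantom(phantomSpec(noiseSD = 0), "deep_end_expiration")
#' @export
generatePhantom <- function(spec, phase, subjectID = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  phase <- match.arg(phase, .airwayPhases)
  d <- spec@shape; sp <- spec@spacing
  prof <- .radiusProfile(spec, phase)

  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  cx0 <- d[1] * sp[1] / 2; cy0 <- d[2] * sp[2] / 2
  zfrac <- (seq_len(d[3]) - 1) / max(1, d[3] - 1)
  cx <- cx0 + spec@wobbleAmplitude * sin(2 * pi * spec@wobbleCycles * zfrac)
  cy <- cy0 + spec@wobbleAmplitude * cos(2 * pi * spec@wobbleCycles * zfrac)

  vol <- array(spec@tissueIntensity, d)
  for (z in which(!is.na(prof))) {
    d2 <- outer((xc - cx[z])^2, (yc - cy[z])^2, `+`)
    vol[, , z][d2 <= prof[z]^2] <- spec@airIntensity
  }
  if (spec@noiseSD > 0) {
    set.seed((as.numeric(spec@seed) * 7 + match(phase, .airwayPhases)) %%
             2147483647)
    vol <- vol + array(stats::rnorm(prod(d), sd = spec@noiseSD), d)
  }
  out <- CTVolume(vol, spacing = sp, phase = phase, subjectID = subjectID)
  attr(out, "groundTruth") <- list(
    landmarks = spec@landmarks,
    radius_mm = prof,
    area_mm2 = pi * prof^2)
  out
}

#' Ground truth attached to a generated phantom
#'
#' @param x A [CTVolume-class] produced by [generatePhantom()], or the list
#'   returned by [generateSubject()].
#' @return The ground-truth list, or \code{NULL} if absent.
#' @export
groundTruth <- function(x) {
  if (is.list(x) && !is.null(x$groundTruth)) return(x$groundTruth)
  attr(x, "groundTruth")
}

#' Generate a phantom subject with prescribed per-region collapse
#'
#' Produces the four respiratory-phase volumes of one synthetic subject.
#' Expiratory, calm-breathing radii are the spec's expiratory radii; the
#' deep end-inspiration radius of each region is chosen analytically so the
#' collapse degree hits its target,
#' \eqn{r_{insp} = r_{exp} \sqrt{1 - target}} (areas scale with the square
#' of the radius). The Muller volume uses the inspiratory radii: the
#' maneuver provokes at least the inspiratory collapse.
#'
#' @param spec A [PhantomSpec-class]; its \code{radii} column for deep end
#'   expiration defines the expiratory calibers.
#' @param collapseTargets Named numeric, one target per region of
#'   [airwayRegions()], each \code{< 1}.
#' @param phases Which phases to generate (default all four).
#' @param subjectID Identifier.
#' @return A list: \code{volumes} (named list of [CTVolume-class]),
#'   \code{groundTruth} (targets, landmarks, per-phase radii).
#' @examples
#' sub <- generateSubject(phantomSpec(), c(nasopharyngeal = 0,
#'   posterior_palatal = 0.2, retrolingual = 0.4, laryngopharyngeal = 0.6),
#'   phases = c("deep_end_expiration", "deep_end_inspiration"))
#' @export
generateSubject <- function(spec, collapseTargets,
                            phases = airwayPhases(),
                            subjectID = "subject") {
  stopifnot(is(spec, "PhantomSpec"))
  collapseTargets <- collapseTargets[.airwayRegions]
  if (any(is.na(collapseTargets)))
    stop("collapseTargets must name every region: ",
         paste(.airwayRegions, collapse = ", "))
  if (any(collapseTargets >= 1))
    stop("collapse targets must be < 1")
  rExp <- spec@radii[, "deep_end_expiration"]
  rInsp <- rExp * sqrt(1 - collapseTargets)
  radii <- spec@radii
  radii[, "deep_end_inspiration"] <- rInsp
  radii[, "calm_breathing"] <- rExp
  radii[, "muller"] <- rInsp
  spec@radii <- radii
  validObject(spec)
  phases <- match.arg(phases, .airwayPhases, several.ok = TRUE)
  volumes <- lapply(phases, function(ph)
    generatePhantom(spec, ph, subjectID = subjectID))
  names(volumes) <- phases
  list(volumes = volumes,
       groundTruth = list(collapseTargets = collapseTargets,
                          landmarks = spec@landmarks, radii = radii,
                          spec = spec))
}
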