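# Flock-event presets: one row per empirically observed flock event, with
# the separation radii used when avoiding a single neighbour versus 6-7.
# The target NND values are documented placeholders: the 28-10 value derives
# from the reported empirical volume (1840 m^3 for 1246 birds) via the
# Poisson relation NND = 0.554 * (V/N)^(1/3); the other events scale it by
# the square root of their separation-radius ratio, a damped scaling that
# keeps every event inside the range of nearest-neighbour distances
# observed in wild starling flocks.
.presetTable <- data.frame(
  eventId    = c("28-10", "48-17", "49-05", "69-10"),
  n          = c(1246L, 871L, 797L, 1129L),
  rSepSingle = c(1.75, 1.30, 0.70, 1.55),
  rSepMulti  = c(1.96, 1.45, 0.90, 1.75),
  rH         = c(0.2, 0.2, 0.2, 0.2),
  targetNnd  = c(0.63, 0.54, 0.40, 0.59),
  stringsAsFactors = FALSE
)

#' Flock-event presets
#'
#' Returns the study design row for one of the four flock events
#' (`"28-10"`, `"48-17"`, `"49-05"`, `"69-10"`): flock size, per-condition
#' separation radii, hard-sphere radius, target nearest-neighbour distance
#' and the default measurement protocol (60 s acclimatization, 2 s
#' diffusion window sampled at 0.01 s, 120 s long window).
#'
#' @param eventId one of `"28-10"`, `"48-17"`, `"49-05"`, `"69-10"`.
#' @param targetNnd override the placeholder target NND (m).
#' @param acclimatizationS,diffusionWindowS,longWindowS,sampleDtS protocol
#'   overrides (s).
#' @return a [FlockEventPreset-class].
#' @examples
#' loadPreset("28-10")
#' @export
loadPreset <- function(eventId, targetNnd = NULL, acclimatizationS = 60,
                       diffusionWindowS = 2, longWindowS = 120,
                       sampleDtS = 0.01) {
  row <- .presetTable[.presetTable$eventId == eventId, ]
  if (nrow(row) != 1)
    stop("unknown flock event '", eventId, "'; known: ",
         paste(.presetTable$eventId, collapse = ", "))
  new("FlockEventPreset", eventId = row$eventId, n = row$n,
      rSepSingle = row$rSepSingle, rSepMulti = row$rSepMulti, rH = row$rH,
      targetNnd = if (is.null(targetNnd)) row$targetNnd else as.numeric(targetNnd),
      acclimatizationS = acclimatizationS,
      diffusionWindowS = diffusionWindowS,
      longWindowS = longWindowS, sampleDtS = sampleDtS)
}

#' @describeIn loadPreset the event ids of all known presets.
#' @export
listPresets <- function() .presetTable$eventId

# separation radius for a given number of avoided neighbours: the single-
# neighbour column for kAvoid = 1, the 6-or-7 column for kAvoid >= 6, and a
# linear interpolation in between (the intermediate radii are not tabulated)
presetRSep <- function(preset, kAvoid) {
  if (kAvoid <= 1) return(preset@rSepSingle)
  if (kAvoid >= 6) return(preset@rSepMulti)
  preset@rSepSingle + (preset@rSepMulti - preset@rSepSingle) * (kAvoid - 1) / 5
}

#' Model parameters for a preset and avoidance condition
#'
#' @param preset a [FlockEventPreset-class].
#' @param kAvoid number of neighbours avoided; picks the matching separation
#'   radius column (interpolated for 2-5).
#' @param rSep override the preset separation radius (m), e.g. with a
#'   [calibrateRSep()] result.
#' @param ... further overrides passed to [flockParams()].
#' @return a [FlockParams-class].
#' @export
presetParams <- function(preset, kAvoid = 1L, rSep = NULL, ...) {
  if (is.null(rSep)) rSep <- presetRSep(preset, kAvoid)
  flockParams(rH = preset@rH, rSep = rSep,
              kAvoid = as.integer(kAvoid), ...)
}
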