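#' Persist and reload trajectories
#'
#' Trajectories are stored in a chunked, compressed columnar container
#' (Apache Parquet) in long format -- one row per (frame, bird) with
#' columns `t_s`, `bird_id`, `x`, `y`, `z`, `fx`, `fy`, `fz` -- which
#' round-trips all doubles losslessly. [exportTrajectoryCsv()] writes the
#' same table as RFC-4180 CSV ('.' decimal separator, UTF-8) for
#' interoperability.
#'
#' @param traj a [FlockTrajectory-class].
#' @param path file path.
#' @return `writeTrajectory()` the path, invisibly; `readTrajectory()` the
#'   reconstructed [FlockTrajectory-class].
#' @examples
#' tr <- makeFixture("ballistic", list(n = 3, nFrames = 4), seed = 1)
#' f <- tempfile(fileext = ".parquet")
#' writeTrajectory(tr, f)
#' identical(positions(readTrajectory(f)), positions(tr))
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "FlockTrajectory"))
  arrow::write_parquet(trajectoryTable(traj), path)
  invisible(path)
}

# long-format table of a trajectory (deterministic given content)
trajectoryTable <- function(traj) {
  d <- dim(traj@positions)
  data.frame(
    t_s = rep(traj@times, d[2]),
    bird_id = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(traj@positions[, , 1]),
    y = as.vector(traj@positions[, , 2]),
    z = as.vector(traj@positions[, , 3]),
    fx = as.vector(traj@forwards[, , 1]),
    fy = as.vector(traj@forwards[, , 2]),
    fz = as.vector(traj@forwards[, , 3]))
}

.trajColumns <- c("t_s", "bird_id", "x", "y", "z", "fx", "fy", "fz")

tableToTrajectory <- function(df, what) {
  missing <- setdiff(.trajColumns, names(df))
  if (length(missing))
    stop("malformed trajectory ", what, ": missing dataset(s) ",
         paste(missing, collapse = ", "))
  times <- sort(unique(df$t_s))
  birds <- sort(unique(df$bird_id))
  tN <- length(times); n <- length(birds)
  if (nrow(df) != tN * n)
    stop("malformed trajectory ", what, ": expected ", tN * n,
         " rows (frames x birds), found ", nrow(df))
  df <- df[order(df$bird_id, df$t_s), ]
  pos <- array(c(df$x, df$y, df$z), dim = c(tN, n, 3))
  fwd <- array(c(df$fx, df$fy, df$fz), dim = c(tN, n, 3))
  new("FlockTrajectory", times = times, positions = pos, forwards = fwd)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- tryCatch(as.data.frame(arrow::read_parquet(path)),
                 error = function(e)
                   stop("malformed trajectory container '", path, "': ",
                        conditionMessage(e)))
  tableToTrajectory(df, "container")
}

#' @rdname writeTrajectory
#' @export
exportTrajectoryCsv <- function(traj, path) {
  data.table::fwrite(trajectoryTable(traj), path)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectoryCsv <- function(path) {
  tableToTrajectory(as.data.frame(data.table::fread(path)), "CSV")
}

#' Run records
#'
#' A run record snapshots everything needed to reproduce a run -- the flat
#' configuration, the seed and the summary metrics -- plus provenance
#' (package version). Stored as JSON.
#'
#' @param config flat named list of configuration keys.
#' @param seed integer seed of the run.
#' @param summary named list of summary metrics (scalars).
#' @param path file path.
#' @return `writeRunRecord()` the path invisibly; `readRunRecord()` the
#'   record as a list.
#' @export
writeRunRecord <- function(config, seed, summary, path) {
  rec <- list(version = as.character(utils::packageVersion("murmuration")),
              seed = seed, config = config, summary = summary)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunRecord
#' @export
readRunRecord <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read and write flat configuration files
#'
#' Configurations are YAML with a flat namespace and a `schema` version
#' key. Unknown keys raise an error so typos do not silently fall back to
#' defaults.
#'
#' @param path file path.
#' @param config named list of keys (see [defaultConfig()]).
#' @export
readFlockConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$schema <- NULL
  known <- names(defaultConfig())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaultConfig()
  out[names(cfg)] <- cfg
  out
}

#' @rdname readFlockConfig
#' @export
writeFlockConfig <- function(config, path) {
  yaml::write_yaml(c(list(schema = 1L), config), path, precision = 15L)
  invisible(path)
}

#' @rdname readFlockConfig
#' @export
defaultConfig <- function() {
  p <- flockParams()
  list(n_birds = 1246L, k_avoid = p@kAvoid, k_topo = p@kTopo,
       r_h_m = p@rH, r_sep_m = p@rSep,
       w_sep = p@wSep, w_align = p@wAlign, w_cohere = p@wCohere,
       centrality_gain = p@centralityGain, w_noise = p@wNoise,
       reaction_time_s = p@reactionTime, k_topo_mix = p@kTopoMix,
       align_velocity = p@alignVelocity, cruise_spread = p@cruiseSpread,
       cohere_spring = p@cohereSpring,
       cruise_speed_mps = p@cruiseSpeed, mass_kg = p@mass,
       speed_tau_s = p@speedTau,
       roll_in_rate = p@rollInRate, roll_out_rate = p@rollOutRate,
       max_roll_deg = p@maxRoll * 180 / pi,
       fov_half_angle_deg = p@fovHalfAngle * 180 / pi,
       dt_s = 0.01, seed = 1L, target_nnd_m = 0.63)
}

#' @describeIn readFlockConfig build a [FlockParams-class] from a flat
#'   config list.
#' @export
configToParams <- function(config) {
  flockParams(rH = config$r_h_m, rSep = config$r_sep_m,
              kAvoid = config$k_avoid, kTopo = config$k_topo,
              wSep = config$w_sep, wAlign = config$w_align,
              wCohere = config$w_cohere,
              centralityGain = config$centrality_gain,
              wNoise = config$w_noise,
              reactionTime = config$reaction_time_s,
              kTopoMix = config$k_topo_mix,
              alignVelocity = config$align_velocity,
              cruiseSpread = config$cruise_spread,
              cohereSpring = config$cohere_spring,
              fovHalfAngle = config$fov_half_angle_deg * pi / 180,
              cruiseSpeed = config$cruise_speed_mps, mass = config$mass_kg,
              speedTau = config$speed_tau_s,
              rollInRate = config$roll_in_rate,
              rollOutRate = config$roll_out_rate,
              maxRoll = config$max_roll_deg * pi / 180)
}
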