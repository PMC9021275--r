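#' Load a simulation configuration from a YAML file
#'
#' The file holds flat key-value sections mirroring the [sim_config()]
#' arguments: `geometry` (helix and body), `elasticity`, `motor`
#' (`K_m`, `K_c` and a `schedule` list of `{t_start, t_end, tau}` entries or
#' a single `tau`/`duration` pair), `fluid`, `steric`, `stepper` and
#' `output`.  Unknown keys are an error; omitted keys take the package
#' defaults, which are echoed back on the returned object as the attribute
#' `resolved` (a complete key-value list sufficient to reproduce the run).
#'
#' @param path file path
#' @return a [sim_config()] with attribute `resolved`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("geometry", "elasticity", "motor", "fluid", "steric",
             "stepper", "output")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  g <- y$geometry %||% list()
  .check_keys(g, c("radius", "pitch", "k", "L_h", "L_f", "c", "ds", "n_f",
                   "left_handed", "body_length", "body_radius", "n_b"),
              "geometry")
  hx <- do.call(helix_spec, g[intersect(names(g),
          c("radius", "pitch", "k", "L_h", "L_f", "c", "ds", "n_f", "left_handed"))])
  bd <- do.call(body_spec, g[intersect(names(g),
          c("body_length", "body_radius", "n_b"))])
  e <- y$elasticity %||% list()
  .check_keys(e, c("a", "a_hook", "a3", "b"), "elasticity")
  m <- y$motor %||% list()
  .check_keys(m, c("K_m", "K_c", "tau", "duration", "schedule"), "motor")
  sched <- if (!is.null(m$schedule)) {
    motor_schedule(vapply(m$schedule, `[[`, 0, "t_start"),
                   vapply(m$schedule, `[[`, 0, "t_end"),
                   vapply(m$schedule, `[[`, 0, "tau"))
  } else if (!is.null(m$tau)) {
    schedule_constant(m$tau, m$duration %||% 0.05)
  } else NULL
  f <- y$fluid %||% list()
  .check_keys(f, c("mu", "eps_f", "eps_b"), "fluid")
  s <- y$steric %||% list()
  .check_keys(s, c("C", "D", "L_prime", "c_w", "D_w"), "steric")
  st <- y$stepper %||% list()
  .check_keys(st, c("dt", "duration", "K", "K_c", "K_m", "alpha1", "alpha2",
                    "beta", "wall_enabled", "wall_spread", "h0",
                    "initial_rotation_angle", "auto_halve_dt"), "stepper")
  o <- y$output %||% list()
  .check_keys(o, c("record_every", "snap_every"), "output")
  args <- list(helix = hx, body = bd)
  for (k in c("a", "a_hook", "a3", "b")) args[[k]] <- e[[k]]
  args$K_m <- m$K_m; args$K_c <- st$K_c %||% m$K_c
  if (!is.null(sched)) args$schedule <- sched
  for (k in c("mu", "eps_f", "eps_b")) args[[k]] <- f[[k]]
  if (length(s)) args$steric <- do.call(steric_params, s)
  for (k in c("dt", "duration", "K", "alpha1", "alpha2", "beta",
              "wall_enabled", "wall_spread", "h0", "initial_rotation_angle",
              "auto_halve_dt")) args[[k]] <- st[[k]]
  for (k in c("record_every", "snap_every")) args[[k]] <- o[[k]]
  args <- Filter(Negate(is.null), args)
  cfg <- do.call(sim_config, args)
  attr(cfg, "resolved") <- resolved_config(cfg)
  cfg
}

.check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in config section '", section, "': ",
         paste(bad, collapse = ", "))
  }
}

#' Fully resolved key-value echo of a configuration
#'
#' @param config a [sim_config()]
#' @return nested list of all resolved parameter values
#' @export
resolved_config <- function(config) {
  list(geometry = c(config$helix[c("radius", "pitch", "k", "L_h", "L_f",
                                   "c", "ds", "left_handed")],
                    config$body[c("body_length", "body_radius", "n_b")]),
       elasticity = list(a = config$a, a_hook = config$a_hook, a3 = config$a3,
                         b = config$b),
       motor = list(K_m = config$K_m, K_c = config$K_c,
                    schedule = lapply(seq_along(config$schedule$tau),
                      function(i) list(t_start = config$schedule$t_start[i],
                                       t_end = config$schedule$t_end[i],
                                       tau = config$schedule$tau[i]))),
       fluid = list(mu = config$mu, eps_f = config$eps_f,
                    eps_b = config$eps_b),
       steric = unclass(config$steric),
       stepper = list(dt = config$dt, duration = config$duration,
                      K = config$K, alpha1 = config$alpha1,
                      alpha2 = config$alpha2, beta = config$beta,
                      wall_enabled = config$wall_enabled,
                      wall_spread = config$wall_spread, h0 = config$h0,
                      initial_rotation_angle = config$initial_rotation_angle,
                      auto_halve_dt = config$auto_halve_dt),
       output = list(record_every = config$record_every,
                     snap_every = config$snap_every),
       version = as.character(utils::packageVersion("lophoswim")))
}

#' Write / read a trajectory as CSV
#'
#' The CSV holds one row per sample with the record columns (time, body
#' pose as centroid + orientation quaternion, motor axis, forward speed,
#' phases, height and diagnostics); the resolved configuration is embedded
#' as `#`-prefixed YAML header lines so a file is self-describing.
#'
#' @param traj a `lopho_trajectory`
#' @param path output path
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(traj, "config")
  if (!is.null(cfg)) {
    hdr <- strsplit(yaml::as.yaml(resolved_config(cfg)), "\n")[[1]]
    writeLines(paste0("# ", hdr), con)
  }
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  structure(df, class = c("lopho_trajectory", "data.frame"))
}

#' Write points and polylines as legacy ASCII VTK polydata
#'
#' Minimal writer for inspecting geometries (flagellum centreline, body
#' markers) in standard viewers.
#'
#' @param points n x 3 matrix
#' @param lines optional list of integer index vectors (1-based polylines)
#' @param path output path
#' @export
write_vtk_polydata <- function(points, lines = NULL, path) {
  points <- as.matrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lophoswim geometry", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(points))), con)
  utils::write.table(format(points, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(lines)) {
    sz <- sum(vapply(lines, length, 0L) + 1L)
    writeLines(sprintf("LINES %d %d", length(lines), sz), con)
    for (ln in lines) {
      writeLines(paste(c(length(ln), ln - 1L), collapse = " "), con)
    }
  }
  invisible(path)
}
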