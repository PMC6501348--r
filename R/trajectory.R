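## Trajectory container: sampled centre-of-mass kinematics of the dimer.
## samples matrix columns: t, Xbar (3), Vbar (3), R

new_trajectory <- function(samples, t0, model, params, seed,
                           final_state = NULL, counters = NULL) {
  colnames(samples) <- c("t", "Xbar_x", "Xbar_y", "Xbar_z",
                         "Vbar_x", "Vbar_y", "Vbar_z", "R")
  samples[, "t"] <- samples[, "t"] + t0
  structure(list(times = samples[, "t"],
                 Xbar = samples[, 2:4, drop = FALSE],
                 Vbar = samples[, 5:7, drop = FALSE],
                 R = samples[, "R"],
                 model = model, params = params, seed = seed,
                 final_state = final_state, counters = counters),
            class = "dimer_trajectory")
}

#' @export
print.dimer_trajectory <- function(x, ...) {
  cat(sprintf("dimer trajectory (%s): %d samples over t = [%g, %g]\n",
              x$model, length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$counters)) {
    cn <- x$counters
    cat(sprintf("  events: %d collisions, %d insertions, %d deletions\n",
                cn$collisions %||% 0L, cn$insertions %||% 0L,
                cn$deletions %||% 0L))
  }
  invisible(x)
}

#' Convert a dimer trajectory to a data frame
#'
#' @param x a `"dimer_trajectory"`.
#' @param ... unused.
#' @return Data frame with columns `t`, `Xbar_{x,y,z}`, `Vbar_{x,y,z}`, `R`.
#' @export
as.data.frame.dimer_trajectory <- function(x, ...) {
  data.frame(t = x$times,
             Xbar_x = x$Xbar[, 1], Xbar_y = x$Xbar[, 2], Xbar_z = x$Xbar[, 3],
             Vbar_x = x$Vbar[, 1], Vbar_y = x$Vbar[, 2], Vbar_z = x$Vbar[, 3],
             R = x$R)
}

#' Write a trajectory to disk
#'
#' Writes the sampled kinematics as a CSV table and a JSON metadata sidecar
#' (`<path>.meta.json`) holding the model tag, parameters and seed.
#'
#' @param traj a `"dimer_trajectory"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(model = traj$model, seed = traj$seed,
               params = serialize_params(traj$params),
               counters = traj$counters)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

serialize_params <- function(p) {
  rapply(p, function(x) if (is.numeric(x) || is.character(x) ||
                            is.logical(x)) x else NULL,
         how = "list")
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path previously passed to [write_trajectory()].
#' @return A `"dimer_trajectory"` (parameters restored as plain lists).
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(times = df$t,
                 Xbar = as.matrix(df[, c("Xbar_x", "Xbar_y", "Xbar_z")]),
                 Vbar = as.matrix(df[, c("Vbar_x", "Vbar_y", "Vbar_z")]),
                 R = df$R,
                 model = meta$model %||% "unknown",
                 params = meta$params, seed = meta$seed,
                 final_state = NULL, counters = meta$counters),
            class = "dimer_trajectory")
}
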