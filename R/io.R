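#' Write a trajectory as XYZ with a CSV tension sidecar
#'
#' One model per frame in plain XYZ (element tag `C` for every bead, comment
#' line carrying the frame time); A2 spring tensions go to
#' `<file>.tensions.csv` (columns `frame`, `time`, `spring`, `tension_pN`)
#' and the parameters to `<file>.params.json`.
#'
#' @param traj a [vwf_trajectory()].
#' @param file output XYZ path.
#' @return `file`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, file) {
  n <- dim(traj$positions)[2]
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t=%.9g s replica=%d", traj$times[i], traj$replica),
               con)
    writeLines(sprintf("C %.6f %.6f %.6f", traj$positions[i, , 1],
                       traj$positions[i, , 2], traj$positions[i, , 3]), con)
  }
  ten <- traj$tensions
  sidecar <- data.frame(
    frame = rep(seq_along(traj$times), each = ncol(ten)),
    time = rep(traj$times, each = ncol(ten)),
    spring = rep(seq_len(ncol(ten)), times = nrow(ten)),
    tension_pN = as.vector(t(ten)))
  utils::write.csv(sidecar, paste0(file, ".tensions.csv"), row.names = FALSE)
  pj <- traj$params
  pj$hi_mode <- as.character(pj$hi_mode)
  jsonlite::write_json(unclass(pj), paste0(file, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a dataset as CSV plus a JSON manifest
#'
#' Features, responses and split assignment in one CSV (a row per
#' observation); the reported feature index map and class counts go to
#' `<file>.manifest.json`.
#'
#' @param dataset an [a2_dataset][build_dataset()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_dataset_csv <- function(dataset, file) {
  df <- data.frame(dataset$features, check.names = FALSE)
  df <- cbind(df, dataset$responses)
  if (!is.null(dataset$split)) df$split <- as.character(dataset$split)
  utils::write.csv(df, file, row.names = FALSE)
  y <- dataset$responses
  manifest <- list(
    resolution = dataset$resolution,
    n_observations = nrow(df),
    seed = dataset$seed,
    class_counts = as.list(colSums(y)),
    index_map = dataset$index_map)
  jsonlite::write_json(manifest, paste0(file, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}
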