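#' Read and write trajectory tables
#'
#' Trajectory ensembles are exchanged as tab-delimited UTF-8 tables with a
#' single header row and columns `particle_id`, `t_s`, `x_um` and optionally
#' `phase` (`run`/`rest`). Units are seconds and micrometres, stated in the
#' headers; the time grid is stored explicitly so acquisition gaps are
#' visible. `read_trajectories()` validates that every particle sits on the
#' same strictly increasing constant-step grid and reports the offending
#' particle on failure.
#'
#' @param path File path.
#' @param ens An `mrnp_ensemble`.
#' @return `read_trajectories()` returns an `mrnp_ensemble` (with `params`
#'   unset); `write_trajectories()` returns `path` invisibly.
#' @name trajectory_io
#' @export
write_trajectories <- function(ens, path) {
  stopifnot(inherits(ens, "mrnp_ensemble"))
  n <- nrow(ens$positions)
  m <- ncol(ens$positions)
  df <- data.frame(
    particle_id = rep(seq_len(n), each = m),
    t_s = rep(ens$times, n),
    x_um = as.vector(t(ens$positions))
  )
  if (!is.null(ens$labels))
    df$phase <- ifelse(as.vector(t(ens$labels)) == 1L, "run", "rest")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("particle_id", "t_s", "x_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory table is missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(df$particle_id)
  first <- df$t_s[df$particle_id == ids[1L]]
  if (length(first) < 2L) stop("particle ", ids[1L], " has fewer than 2 samples")
  steps <- diff(first)
  dt <- steps[1L]
  for (id in ids) {
    tt <- df$t_s[df$particle_id == id]
    d <- diff(tt)
    if (any(d <= 0))
      stop("non-monotone time grid for particle ", id)
    if (any(abs(d - dt) > 1e-6 * dt))
      stop("irregular time step (gap or mixed dt) for particle ", id)
    if (length(tt) != length(first) || any(abs(tt - first) > 1e-6 * dt))
      stop("particle ", id, " is not on the shared time grid")
  }
  m <- length(first)
  X <- matrix(df$x_um, ncol = m, byrow = TRUE)
  L <- NULL
  if ("phase" %in% names(df))
    L <- matrix(as.integer(df$phase == "run"), ncol = m, byrow = TRUE)
  structure(list(times = first - first[1L], positions = X, labels = L,
                 params = NULL, aging_time = NA_real_,
                 window = first[m] - first[1L], dt = dt, noise = NULL,
                 true_segments = NULL),
            class = "mrnp_ensemble")
}

#' Read and write phase-segment tables
#'
#' Segment tables (one row per run or rest phase) are exchanged as
#' tab-delimited tables with columns `particle_id`, `kind`, `t_start`,
#' `t_end`, `duration`, `dx`, `v_run`, `left_censored`, `right_censored`.
#'
#' @param segments A segment table.
#' @param path File path.
#' @name segment_io
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname segment_io
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("particle_id", "kind", "t_start", "t_end", "duration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read and write smFISH spot tables
#'
#' Spot tables are tab-delimited with columns `dendrite_id`, `species`
#' (optional), `x_um`, `y_um`, `z_um`; dendrite lengths travel in a separate
#' two-column table (`dendrite_id`, `length_um`).
#'
#' @param spots A spot table.
#' @param path File path.
#' @name spot_io
#' @export
write_spots <- function(spots, path) {
  check_spot_table(spots)
  utils::write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spot_io
#' @export
read_spots <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_spot_table(df)
  df
}

#' Read and write run manifests
#'
#' Every dataset-producing step emits a JSON manifest holding the tool
#' version, the fully resolved configuration (including the seed) and the
#' files written, sufficient to regenerate the outputs exactly.
#'
#' @param manifest A named list.
#' @param path File path.
#' @name manifest_io
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
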