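#' Scenario configuration for synthetic trajectory datasets
#'
#' Resolves a species preset, parameter overrides, an aging specification
#' (single aging time or a two-population mixture), a noise specification and
#' a seed into one fully concrete, serializable configuration. The same
#' configuration regenerates the identical dataset.
#'
#' @param species `"beta_actin"`, `"arc"` or `"custom"`.
#' @param params Optional [levy_walk_params()] overriding the preset
#'   (required when `species = "custom"`).
#' @param aging Either `list(ta = <s>)` or
#'   `list(w_new =, ta_new =, ta_old =)` for a mixture.
#' @param n_traj Number of trajectories.
#' @param window Observation window (s).
#' @param noise `NULL`, or `list(type = "white", sigma =)` /
#'   `list(type = "ar1", sigma =, phi =)`.
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config("arc", aging = list(ta = 30), n_traj = 100, seed = 7)
scenario_config <- function(species = c("beta_actin", "arc", "custom"),
                            params = NULL, aging = list(ta = 100),
                            n_traj = 1000, window = 60,
                            noise = list(type = "white", sigma = 0.05),
                            seed = 1L) {
  species <- match.arg(species)
  if (is.null(params)) {
    if (species == "custom")
      stop("'params' is required when species = \"custom\"")
    params <- mrnp_preset(species)
  }
  stopifnot(inherits(params, "levy_walk_params"))
  mixture <- all(c("w_new", "ta_new", "ta_old") %in% names(aging))
  if (!mixture && !("ta" %in% names(aging)))
    stop("'aging' must supply either 'ta' or (w_new, ta_new, ta_old)")
  structure(list(species = species, params = unclass(params),
                 aging = aging, mixture = mixture,
                 n_traj = as.integer(n_traj), window = window,
                 noise = noise, seed = as.integer(seed)),
            class = "scenario_config")
}

resolve_noise <- function(spec) {
  if (is.null(spec)) return(NULL)
  switch(spec$type,
         white = noise_white(spec$sigma),
         ar1 = noise_ar1(spec$sigma, spec$phi),
         stop("unknown noise spec type: ", spec$type))
}

#' Generate a synthetic trajectory dataset with ground truth
#'
#' Simulates the configured ensemble, writes the trajectory table, the true
#' phase-segment table (for benchmarking segmentation against known truth)
#' and a JSON manifest recording the full resolved configuration. Re-running
#' with the same configuration reproduces the files byte for byte.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the `ensemble`, the `files` written and
#'   the `config`.
#' @export
make_trajectory_dataset <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  params <- do.call(levy_walk_params, config$params)
  noise <- resolve_noise(config$noise)
  ens <- if (config$mixture) {
    simulate_mixture(params, config$aging$w_new, config$aging$ta_new,
                     config$aging$ta_old, config$n_traj, config$window,
                     noise = noise)
  } else {
    simulate_trajectories(params, config$n_traj, config$aging$ta,
                          config$window, noise = noise, ground_truth = TRUE)
  }
  files <- c(trajectories = file.path(dir, "trajectories.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_trajectories(ens, files[["trajectories"]])
  if (!is.null(ens$true_segments)) {
    files <- c(files, segments_truth = file.path(dir, "segments_truth.tsv"))
    write_segments(ens$true_segments, files[["segments_truth"]])
  }
  write_manifest(list(tool = "mrnpwalk",
                      version = as.character(utils::packageVersion("mrnpwalk")),
                      step = "make_trajectory_dataset",
                      config = unclass(config),
                      files = as.list(files)),
                 files[["manifest"]])
  invisible(list(ensemble = ens, files = files, config = config))
}

#' Generate a synthetic smFISH spot field with planted colocalization
#'
#' Emulates two-color smFISH spot tables over a set of dendrites: spot
#' counts per dendrite are Poisson at the given linear densities, positions
#' are uniform in a dendrite-shaped slab (stated length, 2 x 2 um cross
#' section; only inter-spot distances matter). Exactly `planted_coloc` query
#' spots are placed within the colocalization threshold of a reference spot;
#' every other query spot is kept at least `min_sep` away from all reference
#' spots, so the planted count is recovered exactly at the threshold.
#'
#' @param n_dendrites Number of dendrites.
#' @param length_um Dendrite length (um), recycled across dendrites.
#' @param density_reference,density_query Linear spot densities (per um).
#' @param n_reference,n_query Optional exact total spot counts; when given,
#'   the corresponding density is ignored and the total is allocated across
#'   dendrites multinomially in proportion to length (use to reproduce a
#'   field with a stated number of observed spots).
#' @param planted_coloc Number of query spots planted within the threshold.
#' @param threshold Colocalization distance (um).
#' @param min_sep Minimum distance (um) of non-planted query spots from any
#'   reference spot (must exceed `threshold`).
#' @param max_tries Resampling attempts per offending spot before declaring
#'   the field infeasible.
#' @return A list: `reference` and `query` spot tables (with `species`
#'   columns), `lengths`, and the planting bookkeeping in `planted`.
#' @export
#' @examples
#' set.seed(7)
#' f <- make_fish_dataset(n_dendrites = 5, planted_coloc = 1)
#' coloc_fraction(nearest_neighbor_distances(f$query, f$reference))
make_fish_dataset <- function(n_dendrites = 54, length_um = 35,
                              density_reference = 0.99,
                              density_query = 0.72,
                              n_reference = NULL, n_query = NULL,
                              planted_coloc = 0, threshold = 0.25,
                              min_sep = 0.3, max_tries = 1000) {
  stopifnot(n_dendrites >= 1, density_reference >= 0, density_query >= 0,
            min_sep > threshold)
  len <- rep_len(length_um, n_dendrites)
  counts_for <- function(total, density) {
    if (is.null(total)) stats::rpois(n_dendrites, density * len)
    else as.integer(stats::rmultinom(1, total, prob = len))
  }
  n_ref_d <- counts_for(n_reference, density_reference)
  n_qry_d <- counts_for(n_query, density_query)
  rand_spots <- function(dend, n, L) {
    data.frame(dendrite_id = rep(dend, n),
               x_um = stats::runif(n, 0, L),
               y_um = stats::runif(n, 0, 2),
               z_um = stats::runif(n, 0, 2))
  }
  ref <- list(); qry <- list()
  for (d in seq_len(n_dendrites)) {
    ref[[d]] <- rand_spots(d, n_ref_d[d], len[d])
    qry[[d]] <- rand_spots(d, n_qry_d[d], len[d])
  }
  reference <- do.call(rbind, ref)
  query <- do.call(rbind, qry)
  if (planted_coloc > nrow(query))
    stop("cannot plant more colocalized spots than query spots exist")
  if (planted_coloc > 0 && nrow(reference) == 0L)
    stop("cannot plant colocalized spots without reference spots")
  # push every query spot out to min_sep first, then plant exact pairs
  for (tries in seq_len(max_tries)) {
    nn <- nearest_neighbor_distances(query, reference)
    bad <- which(!nn$no_reference & nn$distance_um < min_sep)
    if (!length(bad)) break
    if (tries == max_tries)
      stop("field too dense: could not keep query spots ", min_sep,
           " um away from reference spots")
    for (i in bad) {
      d <- query$dendrite_id[i]
      query[i, c("x_um", "y_um", "z_um")] <-
        c(stats::runif(1, 0, len[d]), stats::runif(1, 0, 2), stats::runif(1, 0, 2))
    }
  }
  planted_idx <- integer(0)
  if (planted_coloc > 0) {
    # only dendrites that contain reference spots can host a planted pair
    eligible <- which(query$dendrite_id %in% unique(reference$dendrite_id))
    if (length(eligible) < planted_coloc)
      stop("not enough query spots in dendrites with reference spots")
    planted_idx <- sample(eligible, planted_coloc)
    for (i in planted_idx) {
      anchors <- which(reference$dendrite_id == query$dendrite_id[i])
      a <- reference[sample(anchors, 1L), c("x_um", "y_um", "z_um")]
      dir3 <- stats::rnorm(3)
      dir3 <- dir3 / sqrt(sum(dir3^2))
      r <- stats::runif(1, 0.2, 0.8) * threshold
      query[i, c("x_um", "y_um", "z_um")] <- as.numeric(a) + r * dir3
    }
  }
  query$species <- "query"
  reference$species <- "reference"
  rownames(query) <- rownames(reference) <- NULL
  list(reference = reference, query = query,
       lengths = data.frame(dendrite_id = seq_len(n_dendrites),
                            length_um = len),
       planted = list(count = planted_coloc, index = sort(planted_idx),
                      threshold = threshold, min_sep = min_sep))
}
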