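#' Nearest-neighbor distances between two spot populations
#'
#' For every query spot, the Euclidean 3-D distance to the nearest reference
#' spot within the same dendrite. The search is never performed across
#' dendrites; query spots in a dendrite with no reference spots are flagged
#' (`no_reference = TRUE`, distance `NA`) rather than dropped.
#'
#' @param query,reference Spot tables: data frames with columns
#'   `dendrite_id`, `x_um`, `y_um`, `z_um` (a `species` column is allowed
#'   and ignored).
#' @return A data frame aligned to `query` rows: `dendrite_id`,
#'   `distance_um`, `no_reference`.
#' @export
#' @examples
#' q <- data.frame(dendrite_id = 1, x_um = 0, y_um = 0, z_um = 0)
#' r <- data.frame(dendrite_id = 1, x_um = c(0.3, 1), y_um = 0, z_um = 0)
#' nearest_neighbor_distances(q, r)
nearest_neighbor_distances <- function(query, reference) {
  check_spot_table(query)
  check_spot_table(reference)
  d <- rep(NA_real_, nrow(query))
  flag <- rep(FALSE, nrow(query))
  for (dend in unique(query$dendrite_id)) {
    qi <- which(query$dendrite_id == dend)
    ri <- which(reference$dendrite_id == dend)
    if (!length(ri)) {
      flag[qi] <- TRUE
      next
    }
    qm <- as.matrix(query[qi, c("x_um", "y_um", "z_um")])
    rm_ <- as.matrix(reference[ri, c("x_um", "y_um", "z_um")])
    # brute force: spot counts per dendrite are tens
    d2 <- outer(rowSums(qm^2), rowSums(rm_^2), `+`) - 2 * qm %*% t(rm_)
    d[qi] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  data.frame(dendrite_id = query$dendrite_id, distance_um = d,
             no_reference = flag)
}

#' Colocalized fraction at a distance threshold
#'
#' Counts query spots whose nearest-neighbor distance is strictly below the
#' threshold (ties at exactly the threshold are not colocalized, matching a
#' "shorter than" criterion). Flagged spots (no reference available) count in
#' the denominator but can never be colocalized.
#'
#' @param distances Numeric distances in um, or the data frame returned by
#'   [nearest_neighbor_distances()].
#' @param threshold Colocalization distance in um (default 0.25, the optical
#'   diffraction limit scale).
#' @return A list: `count`, `n`, `percent`.
#' @export
#' @examples
#' coloc_fraction(c(0.1, 0.3, 0.5))   # 1 of 3
coloc_fraction <- function(distances, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  if (is.data.frame(distances)) distances <- distances$distance_um
  n <- length(distances)
  count <- sum(distances < threshold, na.rm = TRUE)
  list(count = count, n = n, percent = 100 * count / n)
}

#' Linear spot density per dendrite
#'
#' Counts spots per dendrite, divides by the dendrite length, and averages
#' the density across dendrites (mean and standard error of the mean).
#' Dendrites present in the length table but without spots contribute a
#' density of zero.
#'
#' @param spots A spot table (see [nearest_neighbor_distances()]).
#' @param lengths Data frame with columns `dendrite_id` and `length_um`
#'   (> 0).
#' @return A list: `per_dendrite` (data frame `dendrite_id`, `count`,
#'   `length_um`, `density`), `mean`, `sem`, `n_dendrites`.
#' @export
linear_density <- function(spots, lengths) {
  check_spot_table(spots)
  stopifnot(is.data.frame(lengths),
            all(c("dendrite_id", "length_um") %in% names(lengths)))
  if (any(lengths$length_um <= 0)) stop("dendrite lengths must be > 0")
  if (anyDuplicated(lengths$dendrite_id))
    stop("duplicated dendrite_id in the length table")
  cnt <- table(factor(spots$dendrite_id, levels = lengths$dendrite_id))
  per <- data.frame(dendrite_id = lengths$dendrite_id,
                    count = as.integer(cnt),
                    length_um = lengths$length_um)
  per$density <- per$count / per$length_um
  list(per_dendrite = per,
       mean = mean(per$density),
       sem = stats::sd(per$density) / sqrt(nrow(per)),
       n_dendrites = nrow(per))
}

check_spot_table <- function(x) {
  need <- c("dendrite_id", "x_um", "y_um", "z_um")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("spot table must be a data frame with columns ",
         paste(need, collapse = ", "))
  xyz <- as.matrix(x[, c("x_um", "y_um", "z_um")])
  if (nrow(x) && !all(is.finite(xyz))) stop("spot coordinates must be finite")
  invisible(x)
}
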