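#' Published distance-ring visit scales
#'
#' Inner ring boundaries (miles) and the dimensionless visit-probability
#' scale for each ring, as tabulated for a New York City safe-injection
#' facility survey and applied here around the candidate OPS. The first
#' ring is closed `[0, 0.25]`; every other ring is half-open `(a, b]`; the
#' last ring is open-ended (`> 6` miles). The published table skips the
#' `(3, 3.5]` interval; for exhaustive binning that ring is restored with a
#' geometrically interpolated scale `sqrt(0.09 * 0.051) ~= 0.0677`,
#' consistent with the exponential distance decay of the neighbouring
#' rings.
#'
#' @format `ring_boundaries_default` is a numeric vector of 14 boundaries
#'   (0 to `Inf`); `ring_visit_scales_default` is a numeric vector of 13
#'   per-ring scales.
#' @export
ring_boundaries_default <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5,
                             4, 5, 6, Inf)

#' @rdname ring_boundaries_default
#' @export
ring_visit_scales_default <- c(1, 0.85, 0.72, 0.58, 0.47, 0.29, 0.18, 0.09,
                               sqrt(0.09 * 0.051), 0.051, 0.023, 0.010,
                               0.0027)

#' Distance-ring profile around the OPS
#'
#' A `ring_profile` couples contiguous distance rings with (i) the
#' dimensionless visit scale of each ring (multiplied by `base_visit_prob`
#' to give the per-use probability of attempting to use at the OPS) and
#' (ii) the fraction of the user population living in each ring.
#'
#' @param boundaries Strictly increasing numeric vector of ring boundaries
#'   in miles, starting at 0; the last boundary may be `Inf` (open-ended
#'   outermost ring). Length is one more than the number of rings.
#' @param visit_scale Non-increasing per-ring scale factors in \[0, 1\].
#' @param population_proportion Per-ring population fractions summing to 1.
#' @param base_visit_prob Attempt probability in the innermost ring
#'   (default 0.67).
#' @return An object of class `ring_profile`.
#' @examples
#' rp <- ring_profile(c(0, 1, Inf), c(1, 0.1), c(0.3, 0.7))
#' visit_probability(rp, 1)   # 0.67
#' @export
ring_profile <- function(boundaries = ring_boundaries_default,
                         visit_scale = ring_visit_scales_default,
                         population_proportion,
                         base_visit_prob = 0.67) {
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0) ||
      boundaries[1] != 0)
    stop("boundaries must start at 0 and be strictly increasing", call. = FALSE)
  k <- length(boundaries) - 1L
  if (length(visit_scale) != k)
    stop("visit_scale must have one entry per ring", call. = FALSE)
  if (any(visit_scale < 0) || any(visit_scale > 1))
    stop("visit_scale entries must lie in [0, 1]", call. = FALSE)
  if (any(diff(visit_scale) > 1e-12))
    stop("visit_scale must be non-increasing with distance", call. = FALSE)
  if (length(population_proportion) != k || any(population_proportion < 0))
    stop("population_proportion must be nonnegative, one entry per ring",
         call. = FALSE)
  if (abs(sum(population_proportion) - 1) > 1e-9)
    stop("population_proportion must sum to 1", call. = FALSE)
  if (base_visit_prob < 0 || base_visit_prob > 1)
    stop("base_visit_prob must be a probability", call. = FALSE)
  structure(list(boundaries = as.numeric(boundaries),
                 visit_scale = as.numeric(visit_scale),
                 population_proportion = as.numeric(population_proportion),
                 base_visit_prob = base_visit_prob),
            class = "ring_profile")
}

#' @rdname ring_profile
#' @param profile A `ring_profile`.
#' @export
n_rings <- function(profile) length(profile$boundaries) - 1L

#' Per-ring probability of attempting to use at the OPS
#'
#' `base_visit_prob * visit_scale[ring]`; e.g. 0.67 in the innermost ring
#' and 0.67 x 0.0027 beyond six miles.
#'
#' @param profile A [ring_profile()].
#' @param ring_index Ring index (1-based) or vector of indices.
#' @return Probability (vector) of attempting the OPS on a use occasion.
#' @export
visit_probability <- function(profile, ring_index) {
  k <- n_rings(profile)
  if (any(ring_index < 1) || any(ring_index > k) ||
      any(ring_index != round(ring_index)))
    stop("ring_index out of range", call. = FALSE)
  profile$base_visit_prob * profile$visit_scale[ring_index]
}

#' Map distances to ring indices
#'
#' The first ring is closed `[0, b1]`; all subsequent rings are half-open
#' `(a, b]`, so a record exactly on a boundary belongs to the inner ring.
#' Every nonnegative distance maps to exactly one ring.
#'
#' @param distance_miles Nonnegative distances in miles.
#' @param profile A [ring_profile()].
#' @return Integer ring indices.
#' @export
assign_ring <- function(distance_miles, profile) {
  if (any(distance_miles < 0) || any(is.na(distance_miles)))
    stop("distances must be nonnegative", call. = FALSE)
  finite_bounds <- profile$boundaries[is.finite(profile$boundaries)]
  idx <- findInterval(distance_miles, finite_bounds, left.open = TRUE)
  pmax(1L, pmin(idx, n_rings(profile)))
}

#' Fit an exponential distance-decay rate to visit scales
#'
#' Least squares of `log(scale)` on `-rate * distance` through the origin
#' (the scale at distance 0 is pinned to 1), so
#' `rate = -sum(d * log(s)) / sum(d^2)`. Used to predict the visit scale at
#' distances not tabulated.
#'
#' @param distances Ring midpoints (or any distances) in miles; at least
#'   two distinct values.
#' @param scales Corresponding scale factors in (0, 1].
#' @return A list of class `distance_decay` with elements `rate` (per
#'   mile), `fitted` (predicted scales at the input distances), `residuals`
#'   (log-scale residuals), and `predict(d)` convenience closure.
#' @examples
#' fit_distance_decay(c(1, 2), exp(-c(1, 2)))$rate   # 1
#' @export
fit_distance_decay <- function(distances, scales) {
  if (length(distances) < 2 || length(distances) != length(scales))
    stop("need >= 2 (distance, scale) pairs", call. = FALSE)
  if (any(scales <= 0) || any(scales > 1))
    stop("scales must lie in (0, 1]", call. = FALSE)
  if (length(unique(distances)) < 2 || sum(distances^2) == 0)
    stop("degenerate input: distances must not all coincide", call. = FALSE)
  rate <- -sum(distances * log(scales)) / sum(distances^2)
  fitted <- exp(-rate * distances)
  structure(list(rate = rate,
                 fitted = fitted,
                 residuals = log(scales) - log(fitted),
                 predict = function(d) exp(-rate * d)),
            class = "distance_decay")
}

#' Ring midpoints of a profile
#'
#' Midpoint of each finite ring; for an open-ended outermost ring the
#' midpoint is taken one half ring-width beyond the last finite boundary.
#' @param profile A [ring_profile()].
#' @return Numeric vector of midpoints in miles.
#' @export
ring_midpoints <- function(profile) {
  b <- profile$boundaries
  k <- n_rings(profile)
  mid <- (b[-length(b)] + b[-1]) / 2
  if (!is.finite(b[length(b)])) {
    w <- b[k] - b[k - 1]
    mid[k] <- b[k] + w / 2
  }
  mid
}

#' Estimate ring population proportions from overdose records
#'
#' Bins each record by its distance from the candidate site and normalises
#' the per-ring counts to sum to 1; this implements the assumption that the
#' user population is distributed proportionally to observed overdoses.
#'
#' @param records A data frame of overdose records with a `distance_miles`
#'   column (see [generate_records()]), or a numeric vector of distances.
#' @param profile A [ring_profile()] supplying the binning.
#' @return Numeric vector of per-ring fractions summing to 1.
#' @export
ring_proportions_from_records <- function(records, profile) {
  d <- if (is.data.frame(records)) records$distance_miles else records
  if (is.null(d) || length(d) == 0)
    stop("no records supplied", call. = FALSE)
  idx <- assign_ring(d, profile)
  counts <- tabulate(idx, nbins = n_rings(profile))
  counts / sum(counts)
}

#' Read / write a ring profile as a delimited-text table
#'
#' The table has columns `ring_lo_miles`, `ring_hi_miles`, `visit_scale`,
#' `population_proportion`; `base_visit_prob` is stored as a column of the
#' same value in every row.
#'
#' @param profile A [ring_profile()].
#' @param path File path for the CSV table.
#' @return `write_ring_profile` returns `path` invisibly;
#'   `read_ring_profile` returns a [ring_profile()].
#' @export
write_ring_profile <- function(profile, path) {
  k <- n_rings(profile)
  df <- data.frame(ring_lo_miles = profile$boundaries[seq_len(k)],
                   ring_hi_miles = profile$boundaries[seq_len(k) + 1L],
                   visit_scale = profile$visit_scale,
                   population_proportion = profile$population_proportion,
                   base_visit_prob = profile$base_visit_prob)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ring_profile
#' @export
read_ring_profile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ring_lo_miles", "ring_hi_miles", "visit_scale",
            "population_proportion", "base_visit_prob")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ring profile table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ring_profile(boundaries = c(df$ring_lo_miles, df$ring_hi_miles[nrow(df)]),
               visit_scale = df$visit_scale,
               population_proportion = df$population_proportion,
               base_visit_prob = df$base_visit_prob[1])
}

#' @export
print.ring_profile <- function(x, ...) {
  k <- n_rings(x)
  hi <- x$boundaries[-1]
  lab <- sprintf("(%g, %g]", x$boundaries[seq_len(k)], hi)
  lab[1] <- sprintf("[0, %g]", hi[1])
  if (!is.finite(hi[k])) lab[k] <- sprintf("> %g", x$boundaries[k])
  cat(sprintf("Ring profile: %d rings, base visit probability %.3g\n",
              k, x$base_visit_prob))
  print(data.frame(ring = lab,
                   visit_scale = x$visit_scale,
                   population = round(x$population_proportion, 4)),
        row.names = FALSE)
  invisible(x)
}
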