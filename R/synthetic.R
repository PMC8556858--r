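#' Default demographic marginals for synthetic overdose records
#'
#' Published marginal shares for Philadelphia overdose decedents and
#' survivors over the study year: sex for both fatal and nonfatal events;
#' race and ethnicity for fatal events only (the nonfatal data carry no
#' race/ethnicity breakdown, so synthetic nonfatal records default to
#' "unknown"). Mean ages are 43.91 (fatal) and 41.5 (nonfatal) years.
#'
#' @return Nested named list of probability vectors and age moments.
#' @export
default_demographic_marginals <- function() {
  list(
    fatal = list(
      sex = c(male = 0.7348, female = 0.2652, unknown = 0),
      race = c(White = 0.6970, Black = 0.2933, `other/unknown` = 0.0097),
      ethnicity = c(Hispanic = 0.1278, `non-Hispanic` = 0.8616,
                    unknown = 0.0106),
      age_mean = 43.91, age_sd = 12
    ),
    nonfatal = list(
      sex = c(male = 0.7083, female = 0.2759, unknown = 0.0158),
      race = c(White = 0, Black = 0, `other/unknown` = 1),
      ethnicity = c(Hispanic = 0, `non-Hispanic` = 0, unknown = 1),
      age_mean = 41.5, age_sd = 12
    )
  )
}

#' Calibrate the spatial mixture to two cumulative distance shares
#'
#' The synthetic distance-from-site distribution is a two-component
#' mixture: a near-site exponential with decay `rate` (weight `weight`)
#' plus a uniform far-field component on `(1.5, 10]` miles. The two free
#' parameters are solved so the analytic CDF passes exactly through the
#' two calibration targets: `F(1) = target_within_1mi` and
#' `F(1.5) = target_within_1p5mi` (published shares 0.30 and 0.38).
#'
#' @param target_within_1mi Cumulative share of users within 1 mile
#'   (0 < x < 1).
#' @param target_within_1p5mi Cumulative share within 1.5 miles
#'   (strictly larger, < 1).
#' @param far_range Support of the uniform far-field component (miles).
#' @return Object of class `spatial_mixture` with elements `rate`,
#'   `weight`, `far_range`, and closures `cdf(x)` and `sample(n)`.
#' @examples
#' mix <- calibrate_spatial_decay(0.30, 0.38)
#' mix$cdf(1)     # 0.30 (to ~1e-12)
#' mix$cdf(1.5)   # 0.38
#' @export
calibrate_spatial_decay <- function(target_within_1mi = 0.30,
                                    target_within_1p5mi = 0.38,
                                    far_range = c(1.5, 10)) {
  t1 <- target_within_1mi
  t15 <- target_within_1p5mi
  if (!(t1 > 0 && t15 > t1 && t15 < 1))
    stop("infeasible calibration targets: need 0 < share(1 mi) < share(1.5 mi) < 1",
         call. = FALSE)
  ratio <- t15 / t1
  ## (1 - e^{-1.5 r}) / (1 - e^{-r}) decreases from 1.5 (r -> 0) to 1 (r -> Inf)
  if (ratio >= 1.5)
    stop("infeasible calibration targets: share(1.5)/share(1) must be < 1.5",
         call. = FALSE)
  g <- function(r) (1 - exp(-1.5 * r)) / (1 - exp(-r)) - ratio
  rate <- stats::uniroot(g, c(1e-9, 200), tol = 1e-14)$root
  weight <- t1 / (1 - exp(-rate))
  if (weight > 1 + 1e-9)
    stop("infeasible calibration targets: required near-site weight exceeds 1",
         call. = FALSE)
  weight <- min(weight, 1)
  lo <- far_range[1]; hi <- far_range[2]
  cdf <- function(x) {
    far <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
    weight * (1 - exp(-rate * pmax(x, 0))) + (1 - weight) * far
  }
  smp <- function(n) {
    near <- stats::runif(n) < weight
    d <- numeric(n)
    d[near] <- stats::rexp(sum(near), rate = rate)
    d[!near] <- stats::runif(sum(!near), lo, hi)
    d
  }
  structure(list(rate = rate, weight = weight, far_range = far_range,
                 targets = c(t1, t15), cdf = cdf, sample = smp),
            class = "spatial_mixture")
}

sample_category <- function(n, probs) {
  if (n == 0) return(factor(character(0), levels = names(probs)))
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

sample_age <- function(n, mean, sd) {
  a <- stats::rnorm(n, mean, sd)
  while (any(bad <- a <= 10 | a >= 100))
    a[bad] <- stats::rnorm(sum(bad), mean, sd)
  a
}

#' Generate synthetic overdose records
#'
#' Emulates the statistical structure of the restricted record-level
#' overdose data: annual fatal/nonfatal counts, a distance-from-site
#' distribution calibrated to the published cumulative shares, and the
#' published demographic marginals. Distances are drawn from the
#' [calibrate_spatial_decay()] mixture; demographic fields are sampled
#' independently of distance unless `race_distance_gradient > 0`, in which
#' case the White share among fatal records is tilted upward linearly
#' toward the site (a qualitative emulation of the observed concentration
#' of White decedents near the candidate location).
#'
#' @param n_fatal,n_nonfatal Record counts to generate.
#' @param spatial_decay A `spatial_mixture` from
#'   [calibrate_spatial_decay()]; default calibrated to shares 0.30 / 0.38.
#' @param demographic_marginals Marginals as returned by
#'   [default_demographic_marginals()].
#' @param race_distance_gradient Nonnegative tilt; 0 (default) samples race
#'   independent of distance.
#' @param seed Integer seed; the same seed reproduces the records exactly.
#' @return A data frame of class `overdose_records` with columns
#'   `distance_miles`, `fatal`, `sex`, `race`, `ethnicity`, `age_years`.
#' @examples
#' rec <- generate_records(100, 380, seed = 1)
#' table(rec$fatal)
#' @export
generate_records <- function(n_fatal = 1033, n_nonfatal = 3788,
                             spatial_decay = calibrate_spatial_decay(),
                             demographic_marginals = default_demographic_marginals(),
                             race_distance_gradient = 0,
                             seed = 1) {
  stopifnot(n_fatal >= 0, n_nonfatal >= 0, race_distance_gradient >= 0)
  set.seed(seed)
  one_group <- function(n, fatal, m) {
    d <- if (n > 0) spatial_decay$sample(n) else numeric(0)
    race <- sample_category(n, m$race)
    if (fatal && race_distance_gradient > 0 && n > 0) {
      ## linear-in-distance tilt: inside 1.5 miles the White share rises
      ## toward the site; Black and other shares shrink proportionally
      pw <- pmin(1, m$race[["White"]] *
                   (1 + race_distance_gradient * pmax(0, 1 - d / 1.5)))
      rest <- 1 - m$race[["White"]]
      pb <- (1 - pw) * m$race[["Black"]] / rest
      po <- pmax(0, 1 - pw - pb)
      u <- stats::runif(n)
      race <- factor(ifelse(u < pw, "White",
                            ifelse(u < pw + pb, "Black", "other/unknown")),
                     levels = names(m$race))
    }
    data.frame(distance_miles = d,
               fatal = rep(fatal, n),
               sex = sample_category(n, m$sex),
               race = race,
               ethnicity = sample_category(n, m$ethnicity),
               age_years = if (n > 0) sample_age(n, m$age_mean, m$age_sd)
                           else numeric(0))
  }
  rec <- rbind(one_group(n_fatal, TRUE, demographic_marginals$fatal),
               one_group(n_nonfatal, FALSE, demographic_marginals$nonfatal))
  rownames(rec) <- NULL
  class(rec) <- c("overdose_records", "data.frame")
  rec
}

#' Default synthetic ring profile
#'
#' Generates a large synthetic record set (default 60,000 events) with the
#' calibrated spatial mixture, bins it into the published distance rings
#' with [ring_proportions_from_records()], and attaches the published
#' visit scales. This stands in for the unpublished per-ring population
#' percentages; only the two cumulative shares (0.30 within 1 mile, 0.38
#' within 1.5 miles) are calibrated quantities.
#'
#' @param seed Integer seed.
#' @param n Number of synthetic events used for binning (>= 50,000 for the
#'   default profile).
#' @param spatial_decay Optional pre-calibrated `spatial_mixture`.
#' @return A [ring_profile()] with the published boundaries and visit
#'   scales and synthetic population proportions.
#' @export
default_ring_profile <- function(seed = 1, n = 60000,
                                 spatial_decay = calibrate_spatial_decay()) {
  set.seed(seed)
  d <- spatial_decay$sample(n)
  prof0 <- ring_profile(population_proportion =
                          rep(1 / length(ring_visit_scales_default),
                              length(ring_visit_scales_default)))
  prop <- ring_proportions_from_records(d, prof0)
  ring_profile(population_proportion = prop)
}

#' Read / write synthetic overdose records as CSV
#'
#' Columns: `distance_miles` (nonnegative real), `fatal` (logical), `sex`,
#' `race`, `ethnicity` (categories), `age_years` (real).
#'
#' @param records An `overdose_records` data frame.
#' @param path CSV file path.
#' @return `write_records` returns `path` invisibly; `read_records`
#'   returns an `overdose_records` data frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path)
  need <- c("distance_miles", "fatal", "sex", "race", "ethnicity", "age_years")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("record table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$fatal <- as.logical(df$fatal)
  class(df) <- c("overdose_records", "data.frame")
  df
}
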