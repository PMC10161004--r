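# Species temperature indices from occurrence records: simple niche mean,
# modeled niche mean and modeled niche optimum from a presence-vs-background
# smooth along the MAT axis.

#' Simple niche mean
#'
#' Arithmetic mean of mean-annual-temperature values at a species' occurrence
#' records.
#'
#' @param occurrence_mats numeric vector of MAT values (degC) at occurrences.
#' @return mean MAT, degrees C.
#' @export
simple_niche_mean <- function(occurrence_mats) {
  if (length(occurrence_mats) == 0L || !is.numeric(occurrence_mats)) {
    stop("at least one occurrence MAT value is required", call. = FALSE)
  }
  if (any(!is.finite(occurrence_mats))) {
    stop("occurrence MAT values must be finite", call. = FALSE)
  }
  mean(occurrence_mats)
}

#' Fit a thermal response curve from occurrences and background
#'
#' Fits a penalized logistic smooth (via [mgcv::gam()]) of presence
#' (occurrence = 1) versus background (= 0) along the MAT axis and converts
#' the fitted probability to a relative occurrence density via the odds
#' p/(1-p), which is proportional to the occurrence density when the
#' background sample is uniform over the gradient. The curve is evaluated on
#' a regular MAT grid (0.1 degC step by default) spanning the background
#' range.
#'
#' @param occurrence_mats MAT values at occurrences (>= 20 required).
#' @param background_mats MAT values of the background sample; must cover the
#'   occurrence range (occurrences outside it are dropped with a warning).
#' @param smoothness basis dimension of the spline (k in `s()`), controlling
#'   the maximum effective degrees of freedom; the penalty selects the
#'   realized smoothness.
#' @param grid_step grid resolution, degrees C.
#' @return object of class `response_curve`: list(mat_grid, density,
#'   effective_df).
#' @export
fit_response_curve <- function(occurrence_mats, background_mats,
                               smoothness = 10, grid_step = 0.1) {
  if (length(occurrence_mats) < 20L) {
    stop("at least 20 occurrences are required to fit a response curve",
         call. = FALSE)
  }
  if (length(background_mats) < 2L) {
    stop("background sample too small", call. = FALSE)
  }
  rng <- range(background_mats)
  outside <- occurrence_mats < rng[1] | occurrence_mats > rng[2]
  if (any(outside)) {
    warning(sum(outside), " occurrence(s) outside the background MAT range; truncated")
    occurrence_mats <- occurrence_mats[!outside]
    if (length(occurrence_mats) < 20L) {
      stop("fewer than 20 occurrences remain after truncation", call. = FALSE)
    }
  }
  dat <- data.frame(
    mat = c(occurrence_mats, background_mats),
    presence = rep(c(1L, 0L), c(length(occurrence_mats), length(background_mats)))
  )
  k <- min(smoothness, length(unique(dat$mat)) - 1L)
  fit <- mgcv::gam(presence ~ s(mat, k = k), family = stats::binomial(),
                   data = dat, method = "REML")
  grid <- seq(rng[1], rng[2], by = grid_step)
  eta <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(mat = grid),
                                      type = "link"))
  density <- exp(eta)  # odds; strictly positive
  density <- density / max(density)
  structure(list(mat_grid = grid, density = density,
                 effective_df = sum(fit$edf)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("response_curve on [", min(x$mat_grid), ",", max(x$mat_grid),
      "] degC,", length(x$mat_grid), "points, edf", round(x$effective_df, 2), "\n")
  invisible(x)
}

check_curve <- function(curve) {
  if (!inherits(curve, "response_curve")) {
    stop("expected a response_curve object", call. = FALSE)
  }
  if (any(curve$density < 0)) stop("negative density in response curve", call. = FALSE)
  if (sum(curve$density) <= 0) {
    stop("response curve has zero total mass; niche index undefined", call. = FALSE)
  }
  invisible(curve)
}

#' Modeled niche mean: density-weighted mean MAT of a response curve
#'
#' Trapezoidal integration of mat * density over the grid, normalized by the
#' integrated density.
#'
#' @param curve a [fit_response_curve()] result.
#' @return niche mean, degrees C.
#' @export
modeled_niche_mean <- function(curve) {
  check_curve(curve)
  g <- curve$mat_grid
  n <- length(g)
  if (n == 1L) return(g)
  h <- diff(g)
  w <- c(h[1] / 2, (h[-1] + h[-(n - 1)]) / 2, h[n - 1] / 2)  # trapezoid weights
  sum(w * g * curve$density) / sum(w * curve$density)
}

#' Modeled niche optimum: grid argmax of the response curve
#'
#' Ties are broken to the lowest MAT value.
#'
#' @param curve a [fit_response_curve()] result.
#' @return niche optimum, degrees C.
#' @export
modeled_niche_optimum <- function(curve) {
  check_curve(curve)
  curve$mat_grid[which.max(curve$density)]
}

#' Estimate species temperature indices by all three methods
#'
#' @param occurrences data.frame with species_id and mat columns (as written
#'   by the generator's occurrences.csv).
#' @param background_mats background MAT sample shared by all species; by
#'   default a uniform grid over the occurrence range.
#' @param methods subset of c("simple_mean", "modeled_mean",
#'   "modeled_optimum").
#' @param smoothness,grid_step passed to [fit_response_curve()].
#' @return data.frame: species_id, method, value_degC.
#' @export
species_temperature_indices <- function(occurrences, background_mats = NULL,
                                        methods = c("simple_mean", "modeled_mean",
                                                    "modeled_optimum"),
                                        smoothness = 10, grid_step = 0.1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(background_mats)) {
    rng <- range(occurrences$mat)
    background_mats <- seq(rng[1] - 1, rng[2] + 1, by = grid_step)
  }
  need_curve <- any(methods %in% c("modeled_mean", "modeled_optimum"))
  sp <- unique(occurrences$species_id)
  out <- lapply(sp, function(s) {
    mats <- occurrences$mat[occurrences$species_id == s]
    rows <- list()
    if ("simple_mean" %in% methods) {
      rows$simple <- data.frame(species_id = s, method = "simple_mean",
                                value_degC = simple_niche_mean(mats))
    }
    if (need_curve) {
      curve <- fit_response_curve(mats, background_mats,
                                  smoothness = smoothness, grid_step = grid_step)
      if ("modeled_mean" %in% methods) {
        rows$mmean <- data.frame(species_id = s, method = "modeled_mean",
                                 value_degC = modeled_niche_mean(curve))
      }
      if ("modeled_optimum" %in% methods) {
        rows$mopt <- data.frame(species_id = s, method = "modeled_optimum",
                                value_degC = modeled_niche_optimum(curve))
      }
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson correlations among the three index methods
#'
#' @param indices data.frame as returned by [species_temperature_indices()]
#'   with all three methods present for >= 3 species.
#' @return 3x3 symmetric Pearson correlation matrix (diagonal 1).
#' @export
index_correlations <- function(indices) {
  methods <- c("simple_mean", "modeled_mean", "modeled_optimum")
  wide <- stats::reshape(indices[indices$method %in% methods, ],
                         idvar = "species_id", timevar = "method",
                         direction = "wide")
  cols <- paste0("value_degC.", methods)
  if (!all(cols %in% names(wide))) {
    stop("all three index methods are required", call. = FALSE)
  }
  wide <- wide[stats::complete.cases(wide[, cols]), cols]
  if (nrow(wide) < 3L) {
    stop("at least 3 species with all three index values are required",
         call. = FALSE)
  }
  sds <- vapply(wide, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant index vector: Pearson correlation undefined", call. = FALSE)
  }
  m <- stats::cor(as.matrix(wide))
  dimnames(m) <- list(methods, methods)
  m
}

#' Extract one method's indices as a named vector for CTI computation
#'
#' @param indices data.frame from [species_temperature_indices()].
#' @param method which method's values to extract.
#' @return named numeric vector, species_id -> index (degC).
#' @export
index_vector <- function(indices, method = "modeled_mean") {
  sub <- indices[indices$method == method, ]
  if (nrow(sub) == 0L) stop("no indices for method '", method, "'", call. = FALSE)
  stats::setNames(sub$value_degC, sub$species_id)
}
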