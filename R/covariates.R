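# Derived model predictors: sliding-window climate changes, annual climatic
# water deficit, topographic heat load, standardization and binary coding.

#' Sliding-window climate change around a census year
#'
#' Difference between the mean of a climate variable over the 15 years t-4
#' through t+10 and its mean over the 15 years t-19 through t-5, where t is
#' the first-census year. The two inclusive windows average over interannual
#' variability and start before the census interval to allow lagged
#' vegetation responses.
#'
#' @param series data.frame with columns `year` and the requested variable,
#'   for a single plot.
#' @param census_year first-census calendar year t.
#' @param variable column name, e.g. "mat" or "precip".
#' @return late-window mean minus early-window mean, in the variable's units.
#' @export
window_climate_change <- function(series, census_year, variable) {
  if (!variable %in% names(series)) {
    stop("variable '", variable, "' not found in climate series", call. = FALSE)
  }
  needed <- (census_year - 19):(census_year + 10)
  missing_years <- setdiff(needed, series$year)
  if (length(missing_years) > 0L) {
    stop("climate series has gaps in the required window: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  v <- series[[variable]][match(needed, series$year)]
  early <- needed <= census_year - 5
  mean(v[!early]) - mean(v[early])
}

#' Annual climatic water deficit
#'
#' Sum over months of the positive part of potential minus actual
#' evapotranspiration; surplus months (AET >= PET) contribute zero.
#'
#' @param pet_monthly,aet_monthly numeric vectors of 12 monthly values, mm.
#' @return annual CWD, mm.
#' @export
annual_cwd <- function(pet_monthly, aet_monthly) {
  if (length(pet_monthly) != 12L || length(aet_monthly) != 12L) {
    stop("pet_monthly and aet_monthly must each have 12 monthly values",
         call. = FALSE)
  }
  sum(pmax(0, pet_monthly - aet_monthly))
}

#' Topographic heat load
#'
#' McCune-Keon-style index of solar heating from latitude, slope and aspect,
#' with aspect folded about the southwest (225 degree) axis so that
#' southwest-facing slopes receive the maximum load:
#' A' = |180 - |aspect - 225||, and
#' HL = c1 + c2 cos(L)cos(S) + c3 sin(L)sin(S) + c4 cos(A') sin(S)
#' with angles in radians inside the trigonometric terms. The published
#' method has several constant sets; they are exposed via `constants`.
#'
#' @param latitude degrees (30-60 advised).
#' @param slope degrees in [0, 90].
#' @param aspect degrees in [0, 360).
#' @param constants numeric length-4 vector (c1, c2, c3, c4).
#' @return dimensionless heat-load index (vectorized).
#' @export
heat_load <- function(latitude, slope, aspect,
                      constants = c(0.339, 0.808, -0.196, -0.482)) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("latitude out of range", call. = FALSE)
  }
  if (any(!is.finite(slope)) || any(slope < 0) || any(slope > 90)) {
    stop("slope must be in [0, 90] degrees", call. = FALSE)
  }
  if (any(!is.finite(aspect)) || any(aspect < 0) || any(aspect >= 360)) {
    stop("aspect must be in [0, 360) degrees", call. = FALSE)
  }
  rad <- pi / 180
  folded <- abs(180 - abs(aspect - 225)) * rad
  L <- latitude * rad
  S <- slope * rad
  constants[1] + constants[2] * cos(L) * cos(S) +
    constants[3] * sin(L) * sin(S) + constants[4] * cos(folded) * sin(S)
}

#' Center and scale a covariate, retaining the transform
#'
#' Standardizes to mean 0, SD 1 using the sample SD over the analysis set;
#' the stored center/scale allow back-conversion of standardized effect sizes
#' to natural units.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list of class `standardized`: values (z-scores), center, scale.
#' @export
standardize <- function(values) {
  if (length(unique(values[is.finite(values)])) < 2L) {
    stop("standardize() requires at least two distinct values (zero variance)",
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  structure(list(values = (values - m) / s, center = m, scale = s),
            class = "standardized")
}

#' Invert a standardization
#'
#' @param z z-scores.
#' @param transform a `standardized` object (or any list with center/scale).
#' @return values on the original scale.
#' @export
unstandardize <- function(z, transform) {
  z * transform$scale + transform$center
}

#' Code a binary predictor for regression
#'
#' `dummy` leaves 0/1 codes untouched. `weighted_effect` codes category 1 as
#' 1 and category 0 as -n1/n0 (n1, n0 = category counts), so the codes sum to
#' zero over the observations and the model intercept estimates the
#' population mean rather than the reference-category mean.
#'
#' @param values vector of 0/1 (or logical).
#' @param scheme "dummy" or "weighted_effect".
#' @return numeric codes of the same length.
#' @export
encode_binary <- function(values, scheme = c("dummy", "weighted_effect")) {
  scheme <- match.arg(scheme)
  v <- as.numeric(values)
  if (any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("encode_binary() requires strictly binary (0/1) input", call. = FALSE)
  }
  if (scheme == "dummy") return(v)
  n1 <- sum(v == 1)
  n0 <- sum(v == 0)
  if (n0 == 0L) {
    stop("weighted effect coding undefined: no reference-category observations",
         call. = FALSE)
  }
  ifelse(v == 1, 1, -n1 / n0)
}

#' Build the standardized covariate table for the regression stage
#'
#' Assembles one row per subplot with the model's predictors: baseline MAT,
#' precipitation and CWD (x2-x4), their 15-year window changes (x5-x7),
#' topographic heat load (x8), coded fire and insect damage flags (x9-x10)
#' and baseline conifer basal-area fraction (x11). When a climate series is
#' supplied, x5-x7 are computed with [window_climate_change()] and
#' [annual_cwd()]; otherwise the landscape's change fields are used directly.
#' Continuous predictors are centered and scaled (mean 0, SD 1) over the
#' analysis set; the transforms are kept in attribute "scaling" for
#' back-conversion of effect sizes.
#'
#' @param landscape landscape data.frame (one row per subplot).
#' @param conifer_fraction data.frame plot_id, subplot_id, x11 (from
#'   [conifer_basal_fraction()]); NA fractions are left NA and the affected
#'   rows drop out of the model stage.
#' @param climate optional annual climate series (as generated by
#'   [generate_climate_series()]).
#' @param census_year first-census year for the window computation.
#' @param coding binary-predictor coding scheme for fire/insect.
#' @param scale logical; standardize continuous predictors (the model stage
#'   requires standardized input).
#' @param heat_load_constants passed to [heat_load()].
#' @return data.frame: plot_id, subplot_id, x2...x11, with attributes
#'   "scaling" (named list of transforms) and "coding".
#' @export
build_covariates <- function(landscape, conifer_fraction, climate = NULL,
                             census_year = 2005L,
                             coding = c("dummy", "weighted_effect"),
                             scale = TRUE,
                             heat_load_constants = c(0.339, 0.808, -0.196, -0.482)) {
  coding <- match.arg(coding)
  out <- data.frame(plot_id = landscape$plot_id,
                    subplot_id = landscape$subplot_id)
  out$x2 <- landscape$baseline_mat
  out$x3 <- landscape$baseline_precip
  out$x4 <- landscape$baseline_cwd
  if (!is.null(climate)) {
    per_plot <- split(climate, climate$plot_id)
    petc <- paste0("pet_m", 1:12)
    aetc <- paste0("aet_m", 1:12)
    ch <- t(vapply(per_plot, function(s) {
      s$cwd <- vapply(seq_len(nrow(s)), function(i) {
        annual_cwd(as.numeric(s[i, petc]), as.numeric(s[i, aetc]))
      }, numeric(1))
      c(mat = window_climate_change(s, census_year, "mat"),
        precip = window_climate_change(s, census_year, "precip"),
        cwd = window_climate_change(s, census_year, "cwd"))
    }, numeric(3)))
    idx <- match(as.character(out$plot_id), rownames(ch))
    out$x5 <- ch[idx, "mat"]
    out$x6 <- ch[idx, "precip"]
    out$x7 <- ch[idx, "cwd"]
  } else {
    out$x5 <- landscape$mat_change
    out$x6 <- landscape$precip_change
    out$x7 <- landscape$cwd_change
  }
  out$x8 <- heat_load(landscape$latitude, landscape$slope, landscape$aspect,
                      constants = heat_load_constants)
  out$x9 <- encode_binary(as.numeric(landscape$fire), coding)
  out$x10 <- encode_binary(as.numeric(landscape$insect), coding)
  key <- paste(conifer_fraction$plot_id, conifer_fraction$subplot_id)
  out$x11 <- conifer_fraction$x11[match(paste(out$plot_id, out$subplot_id), key)]

  scaling <- list()
  if (scale) {
    for (v in c("x2", "x3", "x4", "x5", "x6", "x7", "x8", "x11")) {
      ok <- is.finite(out[[v]])
      if (length(unique(out[[v]][ok])) < 2L) {
        # constant predictor: center only, so the design stays full rank
        # via the intercept rather than erroring out of the whole table
        ctr <- mean(out[[v]][ok])
        out[[v]][ok] <- out[[v]][ok] - ctr
        scaling[[v]] <- list(center = ctr, scale = 1)
        warning("covariate ", v, " is constant; centered but not scaled")
        next
      }
      tr <- standardize(out[[v]][ok])
      out[[v]][ok] <- tr$values
      scaling[[v]] <- list(center = tr$center, scale = tr$scale)
    }
  }
  attr(out, "scaling") <- scaling
  attr(out, "coding") <- coding
  attr(out, "standardized") <- scale
  out
}
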