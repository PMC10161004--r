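# End-to-end orchestration: simulate -> niche indices -> CTI/decomposition ->
# covariates -> hierarchical fits, with a run manifest, input validation and
# CSV/JSON artifacts.

#' Run the full thermophilization pipeline on synthetic data
#'
#' Generates an inventory, estimates species temperature indices, builds the
#' CTI table and demographic decomposition, derives standardized covariates,
#' and fits the hierarchical regression for each requested response variant.
#' Deterministic under a fixed config seed with empirical-Bayes inference.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, all stage CSVs plus
#'   effects.csv, effects.json and manifest.json are written there.
#' @param niche_method species index used for CTI ("modeled_mean" default;
#'   "simple_mean" skips curve fitting, "modeled_optimum" also available).
#' @param coding binary-predictor coding ("weighted_effect" default, so the
#'   time coefficient is the population-mean thermophilization).
#' @param variants response variants to fit.
#' @param spec a [model_spec()].
#' @param n_occurrences occurrence records per species for niche estimation.
#' @param census_year first-census calendar year.
#' @return invisibly, a list: manifest, indices, cti, decomposition,
#'   covariates, fits (named by variant), effects (the combined
#'   [effect_table()]), thermophilization (the weighted-effect beta1 summary,
#'   when available).
#' @export
run_all <- function(config = simulation_config(), outdir = NULL,
                    niche_method = c("modeled_mean", "simple_mean",
                                     "modeled_optimum"),
                    coding = c("weighted_effect", "dummy"),
                    variants = c("all", "mortality", "growth", "recruitment",
                                 "sapling"),
                    spec = model_spec(),
                    n_occurrences = 500,
                    census_year = 2005L) {
  niche_method <- match.arg(niche_method)
  coding <- match.arg(coding)
  t0 <- Sys.time()
  stage_times <- c()
  tick <- function(name) {
    stage_times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  sim <- simulate_inventory(config, dir = outdir,
                            n_occurrences = n_occurrences,
                            census_year = census_year)
  tick("simulate")

  methods <- if (niche_method == "simple_mean") "simple_mean" else
    unique(c(niche_method))
  indices_df <- species_temperature_indices(sim$occurrences, methods = methods)
  idx <- index_vector(indices_df, niche_method)
  tick("niches")

  trees <- filter_census_trees(sim$trees)
  n_filtered <- nrow(sim$trees) - nrow(trees)
  cti <- cti_table(trees, idx)
  decomp <- decompose(trees, idx)
  tick("cti")

  conifer_flags <- stats::setNames(sim$species$conifer, sim$species$species_id)
  key <- interaction(trees$plot_id, trees$subplot_id, drop = TRUE)
  cf <- do.call(rbind, lapply(split(trees, key), function(sub) {
    data.frame(plot_id = sub$plot_id[1], subplot_id = sub$subplot_id[1],
               x11 = conifer_basal_fraction(
                 sub[sub$size_class == "main", , drop = FALSE], conifer_flags))
  }))
  landscape_cf <- merge(sim$landscape, cf, by = c("plot_id", "subplot_id"),
                        all.x = TRUE)
  landscape_cf <- landscape_cf[order(landscape_cf$plot_id,
                                     landscape_cf$subplot_id), ]
  cf_full <- data.frame(plot_id = landscape_cf$plot_id,
                        subplot_id = landscape_cf$subplot_id,
                        x11 = landscape_cf$x11)
  covariates <- build_covariates(sim$landscape[order(sim$landscape$plot_id,
                                                     sim$landscape$subplot_id), ],
                                 cf_full, climate = sim$climate,
                                 census_year = census_year, coding = coding)
  tick("covariates")

  coords <- sim$landscape[!duplicated(sim$landscape$plot_id),
                          c("plot_id", "x_km", "y_km")]
  fits <- list()
  dropped <- list()
  for (v in variants) {
    des <- build_design(cti, covariates, v)
    if (length(unique(des$plot_id)) < 2L || nrow(des) < 50L) {
      warning("variant '", v, "' has too few usable rows; skipped")
      next
    }
    fits[[v]] <- fit_cti_model(des, coords, spec)
    dropped[[v]] <- attr(des, "dropped")
  }
  tick("fit")

  effects <- effect_table(fits)
  thermo <- if (coding == "weighted_effect" && "all" %in% names(fits)) {
    mean_thermophilization(fits[["all"]])
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("forestcti")),
    seed = config$seed,
    config_hash = config_hash(config),
    stage_seconds = as.list(stage_times),
    rows = list(trees_generated = nrow(sim$trees),
                trees_after_census_filter = nrow(trees),
                trees_filtered_out = n_filtered,
                subplots = nrow(cf_full),
                subplots_decomposed = nrow(decomp),
                subplots_dropped_undefined_cti = attr(decomp, "dropped"),
                design_rows_dropped = dropped),
    variants_fit = names(fits),
    niche_method = niche_method,
    coding = coding,
    headline = if (!is.null(thermo)) {
      list(mean_thermophilization_degC = thermo$estimate,
           rate_degC_per_year = thermo$rate_per_year,
           ci95 = c(thermo$lower, thermo$upper))
    } else NULL
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(indices_df, file.path(outdir, "species_indices.csv"),
                     row.names = FALSE)
    utils::write.csv(cti, file.path(outdir, "cti.csv"), row.names = FALSE)
    utils::write.csv(decomp, file.path(outdir, "decomposition.csv"),
                     row.names = FALSE)
    utils::write.csv(covariates, file.path(outdir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(effects, file.path(outdir, "effects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(effects = effects, manifest = manifest),
                         file.path(outdir, "effects.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(manifest = manifest, sim = sim, indices = indices_df,
                 cti = cti, decomposition = decomp, covariates = covariates,
                 fits = fits, effects = effects, thermophilization = thermo))
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                                   character(1)), sep = "=", collapse = ";")
  # small stable checksum without extra dependencies
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Validate input tables against the pipeline's invariants
#'
#' Checks the tree-table fate partition (survivors have both DBH values,
#' deaths no T2, recruits no T1), size-class DBH bounds, distance bounds, and
#' landscape ranges (slope, aspect, probabilities). Reporting only: returns a
#' machine-readable violations table and never throws.
#'
#' @param trees TreeRecord data.frame.
#' @param landscape optional landscape data.frame.
#' @return data.frame: table, rule, n_violations, example_rows.
#' @export
validate_inputs <- function(trees, landscape = NULL) {
  viol <- list()
  add <- function(table, rule, bad) {
    if (any(bad, na.rm = TRUE)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        table = table, rule = rule, n_violations = sum(bad, na.rm = TRUE),
        example_rows = paste(utils::head(which(bad), 3L), collapse = ","))
    }
  }
  if (!is.null(trees) && nrow(trees) > 0L) {
    add("trees", "fate must be survivor/died/recruit",
        !trees$fate %in% c("survivor", "died", "recruit"))
    add("trees", "recruit must have no dbh_t1",
        trees$fate == "recruit" & !is.na(trees$dbh_t1_cm))
    add("trees", "died must have no dbh_t2",
        trees$fate == "died" & !is.na(trees$dbh_t2_cm))
    add("trees", "survivor must have both dbh values",
        trees$fate == "survivor" & (is.na(trees$dbh_t1_cm) | is.na(trees$dbh_t2_cm)))
    main_dbh <- ifelse(trees$fate == "recruit", trees$dbh_t2_cm, trees$dbh_t1_cm)
    add("trees", "main class requires relevant DBH >= 12.7 cm",
        trees$size_class == "main" & (is.na(main_dbh) | main_dbh < 12.7))
    add("trees", "sapling class requires DBH in [2.5, 12.7)",
        trees$size_class == "sapling" &
          (is.na(main_dbh) | main_dbh < 2.5 | main_dbh >= 12.7))
    add("trees", "distance must be nonnegative",
        is.na(trees$dist_m) | trees$dist_m < 0)
  }
  if (!is.null(landscape) && nrow(landscape) > 0L) {
    add("landscape", "slope must be in [0, 90]",
        is.na(landscape$slope) | landscape$slope < 0 | landscape$slope > 90)
    add("landscape", "aspect must be in [0, 360)",
        is.na(landscape$aspect) | landscape$aspect < 0 | landscape$aspect >= 360)
    key <- paste(landscape$plot_id)
    for (cc in c("x_km", "y_km")) {
      same <- tapply(landscape[[cc]], key, function(v) length(unique(v)) == 1L)
      add("landscape", paste0(cc, " must be identical within a plot"),
          !same[key])
    }
  }
  if (length(viol) == 0L) {
    return(data.frame(table = character(0), rule = character(0),
                      n_violations = integer(0), example_rows = character(0)))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
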