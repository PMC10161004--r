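# Synthetic forest-inventory generator: landscapes, species pools, repeat tree
# censuses, occurrence records and annual climate series with controllable
# effect sizes. All randomness is governed by config$seed (stage-specific
# offsets keep stages independently reproducible).

#' Simulation configuration for the synthetic forest-inventory generator
#'
#' Builds and validates the parameter set controlling every stage of the
#' synthetic data generator. The defaults emulate the observed magnitudes of a
#' western-US repeat-census inventory: plots of four circular 7.32 m-radius
#' subplots, a 12.7 cm diameter-at-breast-height (DBH) census threshold with a
#' 2.5-12.7 cm sapling class, about 7 main-class stems per subplot (roughly
#' 5.6 survivors and 1.1 deaths over a 10-year interval), 0.63 recruits per
#' subplot, and mean warming of 0.32 degrees C per census interval.
#'
#' @param n_plots number of plots.
#' @param n_subplots_per_plot subplots per plot (>= 1).
#' @param n_species species-pool size (>= 2).
#' @param domain_extent_km side length of the square planar domain, km.
#' @param mat_gradient range of baseline mean annual temperature (MAT) across
#'   the domain, degrees C.
#' @param mat_min coolest baseline MAT in the domain, degrees C.
#' @param warming_mean,warming_sd mean and SD of plot-level MAT change per
#'   census interval, degrees C.
#' @param precip_change_mean,precip_change_sd plot-level precipitation change,
#'   mm.
#' @param cwd_change_mean,cwd_change_sd plot-level change in annual climatic
#'   water deficit, mm.
#' @param mortality_niche_bias increase in log-odds of death per degree C the
#'   species optimum falls below the subplot's post-warming temperature
#'   (1/degC). Zero removes the mortality mechanism.
#' @param growth_niche_bias increase in log growth increment per degree C the
#'   species optimum exceeds the subplot's post-warming temperature (1/degC).
#' @param recruit_rate expected recruits into the main size class per subplot.
#' @param fire_prob,insect_prob subplot-level probabilities of binary fire and
#'   insect damage flags.
#' @param fire_mortality_logodds,insect_mortality_logodds additive log-odds of
#'   death on damaged subplots (multiplicative on the odds scale).
#' @param insect_niche_bias extra mortality niche slope (1/degC) on
#'   insect-damaged subplots, biasing deaths toward cool-niche species.
#' @param spatial_sd,spatial_range_km marginal SD (degrees C) and Matern
#'   (nu = 1) range of the spatially autocorrelated plot-level microclimate
#'   effect.
#' @param subplot_sd SD of the iid subplot-level microclimate effect, degrees C.
#' @param residual_sd SD of per-tree noise added to the assembly temperature,
#'   degrees C.
#' @param tree_density_mean Poisson mean of main-class stems per subplot.
#' @param baseline_mortality baseline per-tree death probability over the
#'   interval (before niche/damage effects).
#' @param sapling_rate Poisson mean of baseline sapling records per subplot.
#' @param seedling_rate Poisson mean of baseline seedling tally draws per
#'   subplot.
#' @param recruit_sapling_frac,recruit_seedling_frac fractions of recruits
#'   whose baseline record is a conspecific sapling (else seedling tally, else
#'   not yet germinated).
#' @param niche_breadth SD of the Gaussian occurrence response of each
#'   species, degrees C.
#' @param heat_offset_scale degrees C of assembly-temperature offset per unit
#'   of topographic heat load deviation from its domain mean.
#' @param climate_noise_sd interannual SD added to the generated annual
#'   climate series (0 keeps window changes exactly equal to the landscape's
#'   change fields).
#' @param seed integer seed governing all stages.
#'
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_plots = 100,
                              n_subplots_per_plot = 4,
                              n_species = 30,
                              domain_extent_km = 100,
                              mat_gradient = 10,
                              mat_min = 4,
                              warming_mean = 0.32,
                              warming_sd = 0.1,
                              precip_change_mean = -10,
                              precip_change_sd = 20,
                              cwd_change_mean = 5,
                              cwd_change_sd = 10,
                              mortality_niche_bias = 0.15,
                              growth_niche_bias = 0.05,
                              recruit_rate = 0.63,
                              fire_prob = 0.02,
                              insect_prob = 0.05,
                              fire_mortality_logodds = 0.7,
                              insect_mortality_logodds = 0.7,
                              insect_niche_bias = 0.1,
                              spatial_sd = 0.3,
                              spatial_range_km = 30,
                              subplot_sd = 0.2,
                              residual_sd = 0.3,
                              tree_density_mean = 7,
                              baseline_mortality = 0.16,
                              sapling_rate = 1.5,
                              seedling_rate = 2,
                              recruit_sapling_frac = 0.87,
                              recruit_seedling_frac = 0.09,
                              niche_breadth = 3,
                              heat_offset_scale = 1,
                              climate_noise_sd = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop("invalid simulation_config: field '", field, "' ", why, call. = FALSE)
  }
  counts <- c("n_plots", "n_subplots_per_plot", "n_species")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop_field(f, "must be a single integer")
    }
  }
  if (cfg$n_plots < 1) stop_field("n_plots", "must be >= 1")
  if (cfg$n_subplots_per_plot < 1) stop_field("n_subplots_per_plot", "must be >= 1")
  if (cfg$n_species < 2) stop_field("n_species", "must be >= 2 (community temperature index variation impossible with fewer)")
  nonneg <- c("warming_sd", "precip_change_sd", "cwd_change_sd", "spatial_sd",
              "subplot_sd", "residual_sd", "niche_breadth", "spatial_range_km",
              "domain_extent_km", "recruit_rate", "tree_density_mean",
              "sapling_rate", "seedling_rate", "climate_noise_sd")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_field(f, "must be a single nonnegative number")
    }
  }
  probs <- c("fire_prob", "insect_prob", "baseline_mortality",
             "recruit_sapling_frac", "recruit_seedling_frac")
  for (f in probs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_field(f, "must be a probability in [0, 1]")
    }
  }
  if (cfg$recruit_sapling_frac + cfg$recruit_seedling_frac > 1) {
    stop_field("recruit_seedling_frac",
               "recruit origin fractions must sum to at most 1")
  }
  if (cfg$niche_breadth <= 0) stop_field("niche_breadth", "must be > 0")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_plots, "plots x", x$n_subplots_per_plot,
      "subplots,", x$n_species, "species, seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic landscape of plots and subplots
#'
#' Plots are placed uniformly at random in a square planar domain (km
#' coordinates; Euclidean distances feed the spatial kernel). Baseline MAT
#' varies linearly along the x axis over `mat_gradient` degrees; latitude maps
#' linearly to the y axis (48 degrees N at y = 0 down to 35 at the far edge).
#' Climate changes are drawn from the configured normals at plot level; fire
#' and insect damage flags are Bernoulli at subplot level. A Matern (nu = 1)
#' spatially autocorrelated plot effect and an iid subplot effect (both in
#' degrees C, columns `spatial_effect` and `subplot_effect`) carry the
#' microclimate structure used by [generate_tree_censuses()].
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per subplot: plot_id, subplot_id, x_km,
#'   y_km, latitude, slope, aspect, baseline_mat, baseline_precip,
#'   baseline_cwd, mat_change, precip_change, cwd_change, fire, insect,
#'   spatial_effect, subplot_effect.
#' @export
generate_landscape <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  np <- config$n_plots
  ns <- config$n_subplots_per_plot
  x <- stats::runif(np, 0, config$domain_extent_km)
  y <- stats::runif(np, 0, config$domain_extent_km)
  frac_x <- if (config$domain_extent_km > 0) x / config$domain_extent_km else rep(0.5, np)
  frac_y <- if (config$domain_extent_km > 0) y / config$domain_extent_km else rep(0.5, np)
  baseline_mat <- config$mat_min + config$mat_gradient * frac_x
  latitude <- 48 - 13 * frac_y
  baseline_precip <- pmax(50, stats::rnorm(np, 800, 150))
  baseline_cwd <- pmax(0, stats::rnorm(np, 300, 80))
  mat_change <- stats::rnorm(np, config$warming_mean, config$warming_sd)
  precip_change <- stats::rnorm(np, config$precip_change_mean, config$precip_change_sd)
  cwd_change <- stats::rnorm(np, config$cwd_change_mean, config$cwd_change_sd)
  # spatially autocorrelated plot-level microclimate effect
  if (config$spatial_sd > 0 && np > 1) {
    dmat <- as.matrix(stats::dist(cbind(x, y)))
    sigma <- matern_cov(dmat, sigma_u = config$spatial_sd,
                        rho = max(config$spatial_range_km, 1e-6), nu = 1)
    diag(sigma) <- diag(sigma) + 1e-8 * config$spatial_sd^2
    spatial_effect <- drop(chol(sigma) %*% stats::rnorm(np))
  } else {
    spatial_effect <- rep(0, np)
  }

  idx <- rep(seq_len(np), each = ns)
  n <- np * ns
  out <- data.frame(
    plot_id = idx,
    subplot_id = rep(seq_len(ns), times = np),
    x_km = x[idx],
    y_km = y[idx],
    latitude = latitude[idx],
    slope = stats::runif(n, 0, 40),
    aspect = stats::runif(n, 0, 360) %% 360,
    baseline_mat = baseline_mat[idx],
    baseline_precip = baseline_precip[idx],
    baseline_cwd = baseline_cwd[idx],
    mat_change = mat_change[idx],
    precip_change = precip_change[idx],
    cwd_change = cwd_change[idx],
    fire = stats::runif(n) < config$fire_prob,
    insect = stats::runif(n) < config$insect_prob,
    spatial_effect = spatial_effect[idx],
    subplot_effect = stats::rnorm(n, 0, config$subplot_sd)
  )
  out
}

#' Generate a synthetic species pool with known thermal niches
#'
#' Species optima are spread evenly across the baseline MAT gradient with
#' small jitter, giving ground truth against which the niche estimators can be
#' validated. Conifer status is assigned Bernoulli(0.5).
#'
#' @param config a [simulation_config()].
#' @return data.frame: species_id, true_optimum (degC), niche_breadth (degC),
#'   conifer (logical).
#' @export
generate_species_pool <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed + 1000L)
  k <- config$n_species
  lo <- config$mat_min
  hi <- config$mat_min + config$mat_gradient
  optima <- seq(lo, hi, length.out = k)
  jitter_sd <- config$mat_gradient / (8 * k)
  optima <- pmin(hi, pmax(lo, optima + stats::rnorm(k, 0, jitter_sd)))
  data.frame(
    species_id = sprintf("sp%03d", seq_len(k)),
    true_optimum = optima,
    niche_breadth = rep(config$niche_breadth, k),
    conifer = stats::runif(k) < 0.5
  )
}

# assembly temperature of each subplot at baseline (T1) and after warming (T2)
assembly_temperature <- function(landscape, config) {
  hl <- heat_load(landscape$latitude, landscape$slope, landscape$aspect)
  offset <- config$heat_offset_scale * (hl - mean(hl))
  t1 <- landscape$baseline_mat + landscape$spatial_effect +
    landscape$subplot_effect + offset
  list(t1 = t1, t2 = t1 + landscape$mat_change)
}

# multinomial species draw with Gaussian suitability weights
draw_species <- function(n, temp, pool, residual_sd) {
  if (n == 0L) return(character(0))
  t_tree <- temp + stats::rnorm(n, 0, residual_sd)
  vapply(t_tree, function(tt) {
    w <- exp(-(tt - pool$true_optimum)^2 / (2 * pool$niche_breadth^2))
    if (sum(w) <= 0) w <- rep(1, nrow(pool))
    sample(pool$species_id, 1L, prob = w)
  }, character(1))
}

#' Generate repeat tree censuses for a synthetic landscape
#'
#' Assembles baseline subplot communities by multinomial draws with Gaussian
#' suitability weights around each subplot's assembly temperature (baseline
#' MAT plus spatial, subplot and heat-load microclimate offsets), then applies
#' the interval's demographic processes. Death probability rises by
#' `mortality_niche_bias` log-odds per degree C that a species' optimum falls
#' below the post-warming subplot temperature; fire and insect damage
#' multiply the mortality odds, with insect damage additionally steepening the
#' niche slope (elevated cool-species mortality). Survivor growth increments
#' are lognormal, tilted by `growth_niche_bias` toward warm-niche species.
#' Recruits enter just above the 12.7 cm threshold with species drawn from
#' post-warming suitability. Baseline saplings (2.5-12.7 cm) and seedling
#' tallies are generated alongside so recruit origins can be classified.
#'
#' @param landscape output of [generate_landscape()].
#' @param species_pool output of [generate_species_pool()].
#' @param config the matching [simulation_config()].
#' @return list with elements `trees` (one row per tree: tree_id, plot_id,
#'   subplot_id, species_id, dbh_t1_cm, dbh_t2_cm, dist_m, fate, size_class)
#'   and `seedlings` (plot_id, subplot_id, species_id, count). Seedlings are
#'   counted tallies, not individually marked stems, so they live in their own
#'   table.
#' @export
generate_tree_censuses <- function(landscape, species_pool, config) {
  validate_simulation_config(config)
  if (is.null(landscape) || nrow(landscape) == 0L) {
    stop("empty landscape: generate_landscape() output required", call. = FALSE)
  }
  set.seed(config$seed + 2000L)
  temps <- assembly_temperature(landscape, config)
  base_lo <- stats::qlogis(min(max(config$baseline_mortality, 1e-6), 1 - 1e-6))

  rows <- vector("list", nrow(landscape))
  seedling_rows <- vector("list", nrow(landscape))
  for (r in seq_len(nrow(landscape))) {
    pid <- landscape$plot_id[r]
    sid <- landscape$subplot_id[r]
    t1 <- temps$t1[r]
    t2 <- temps$t2[r]
    fire <- landscape$fire[r]
    insect <- landscape$insect[r]

    n_main <- stats::rpois(1L, config$tree_density_mean)
    sp_main <- draw_species(n_main, t1, species_pool, config$residual_sd)
    opt <- species_pool$true_optimum[match(sp_main, species_pool$species_id)]
    dbh1 <- 12.7 + stats::rlnorm(n_main, meanlog = log(10), sdlog = 0.6)
    dist <- 7.32 * sqrt(stats::runif(n_main))
    niche_gap <- t2 - opt  # positive for cool-niche species under warming
    lo <- base_lo + config$mortality_niche_bias * niche_gap +
      fire * config$fire_mortality_logodds +
      insect * (config$insect_mortality_logodds +
                  config$insect_niche_bias * niche_gap)
    died <- stats::runif(n_main) < stats::plogis(lo)
    growth <- stats::rlnorm(n_main,
                            meanlog = log(1.2) + config$growth_niche_bias * (opt - t2),
                            sdlog = 0.5)
    dbh2 <- ifelse(died, NA_real_, dbh1 + growth)

    n_rec <- stats::rpois(1L, config$recruit_rate)
    sp_rec <- draw_species(n_rec, t2, species_pool, config$residual_sd)
    rec_dbh2 <- 12.7 + stats::rlnorm(n_rec, meanlog = log(0.5), sdlog = 0.5)
    rec_dist <- 7.32 * sqrt(stats::runif(n_rec))

    # sapling census (2.07 m microplot in the field design; here species and
    # sizes only) with the same mortality mechanics, capped below threshold
    n_sap <- stats::rpois(1L, config$sapling_rate)
    sp_sap <- draw_species(n_sap, t1, species_pool, config$residual_sd)
    sap_opt <- species_pool$true_optimum[match(sp_sap, species_pool$species_id)]
    sap_dbh1 <- stats::runif(n_sap, 2.5, 12.69)
    sap_lo <- base_lo + config$mortality_niche_bias * (t2 - sap_opt) +
      fire * config$fire_mortality_logodds +
      insect * (config$insect_mortality_logodds +
                  config$insect_niche_bias * (t2 - sap_opt))
    sap_died <- stats::runif(n_sap) < stats::plogis(sap_lo)
    sap_dbh2 <- ifelse(sap_died, NA_real_,
                       pmin(sap_dbh1 + stats::rlnorm(n_sap, log(0.6), 0.5), 12.69))
    sap_dist <- 2.07 * sqrt(stats::runif(n_sap))

    # recruit-origin bookkeeping: most recruits were baseline saplings, some
    # only conspecific seedlings, the rest not yet germinated
    origin <- stats::runif(n_rec)
    sap_from_rec <- sp_rec[origin < config$recruit_sapling_frac]
    seed_from_rec <- sp_rec[origin >= config$recruit_sapling_frac &
                              origin < config$recruit_sapling_frac +
                              config$recruit_seedling_frac]

    n_seed <- stats::rpois(1L, config$seedling_rate)
    sp_seed <- c(draw_species(n_seed, t1, species_pool, config$residual_sd),
                 seed_from_rec)
    if (length(sp_seed) > 0L) {
      tab <- table(sp_seed)
      seedling_rows[[r]] <- data.frame(
        plot_id = pid, subplot_id = sid,
        species_id = names(tab), count = as.integer(tab),
        row.names = NULL
      )
    }

    nsr <- length(sap_from_rec)
    if (n_main + n_rec + n_sap + nsr == 0L) next
    rows[[r]] <- data.frame(
      plot_id = pid,
      subplot_id = sid,
      species_id = c(sp_main, sp_rec, sp_sap, sap_from_rec),
      dbh_t1_cm = c(dbh1, rep(NA_real_, n_rec), sap_dbh1,
                    if (nsr) stats::runif(nsr, 8, 12.69) else numeric(0)),
      dbh_t2_cm = c(dbh2, rec_dbh2, sap_dbh2, rep(NA_real_, nsr)),
      dist_m = c(dist, rec_dist, sap_dist,
                 if (nsr) 2.07 * sqrt(stats::runif(nsr)) else numeric(0)),
      fate = c(ifelse(died, "died", "survivor"), rep("recruit", n_rec),
               ifelse(sap_died, "died", "survivor"), rep("died", nsr)),
      size_class = c(rep("main", n_main + n_rec), rep("sapling", n_sap + nsr)),
      row.names = NULL
    )
  }
  trees <- do.call(rbind, rows)
  if (is.null(trees)) {
    trees <- data.frame(plot_id = integer(0), subplot_id = integer(0),
                        species_id = character(0), dbh_t1_cm = numeric(0),
                        dbh_t2_cm = numeric(0), dist_m = numeric(0),
                        fate = character(0), size_class = character(0))
  }
  trees <- cbind(tree_id = seq_len(nrow(trees)), trees)
  seedlings <- do.call(rbind, seedling_rows[!vapply(seedling_rows, is.null, logical(1))])
  if (is.null(seedlings)) {
    seedlings <- data.frame(plot_id = integer(0), subplot_id = integer(0),
                            species_id = character(0), count = integer(0))
  }
  list(trees = trees, seedlings = seedlings)
}

#' Generate species occurrence records along a MAT gradient
#'
#' Draws occurrence MAT values for each species with density proportional to a
#' Gaussian response centered on the species' true optimum, truncated to the
#' supplied background grid. These emulate presence records across a species'
#' geographic range and are the input to the niche estimators.
#'
#' @param species_pool output of [generate_species_pool()].
#' @param mat_grid numeric vector of candidate MAT values (the background).
#' @param n_per_species occurrences to draw per species (>= 1).
#' @param seed integer seed.
#' @return data.frame: species_id, mat (degC).
#' @export
generate_occurrences <- function(species_pool, mat_grid, n_per_species, seed = 1L) {
  if (length(mat_grid) == 0L) stop("empty MAT grid", call. = FALSE)
  if (n_per_species < 1) stop("n_per_species must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- lapply(seq_len(nrow(species_pool)), function(i) {
    w <- stats::dnorm(mat_grid, species_pool$true_optimum[i],
                      species_pool$niche_breadth[i])
    if (sum(w) <= 0) w <- rep(1, length(mat_grid))
    data.frame(species_id = species_pool$species_id[i],
               mat = sample(mat_grid, n_per_species, replace = TRUE, prob = w))
  })
  do.call(rbind, out)
}

#' Generate annual climate series consistent with a landscape
#'
#' Produces per-plot annual MAT, precipitation and monthly potential/actual
#' evapotranspiration covering the 30-year span needed by the 15-year
#' sliding-window change computation. Each variable steps from its baseline
#' level (first window) to baseline plus the landscape's change field (second
#' window), so with `climate_noise_sd = 0` the window changes recover the
#' landscape's `mat_change`, `precip_change` and `cwd_change` exactly. Monthly
#' PET-AET is arranged so the annual climatic water deficit equals the
#' intended annual CWD (six deficit months, six surplus months).
#'
#' @param landscape output of [generate_landscape()].
#' @param config the matching [simulation_config()].
#' @param census_year calendar year of the first census.
#' @return data.frame: plot_id, year, mat, precip, pet_m1..pet_m12,
#'   aet_m1..aet_m12.
#' @export
generate_climate_series <- function(landscape, config, census_year = 2005L) {
  validate_simulation_config(config)
  plots <- landscape[!duplicated(landscape$plot_id), , drop = FALSE]
  set.seed(config$seed + 3000L)
  years <- (census_year - 19):(census_year + 10)
  late <- years >= census_year - 4  # second 15-y window
  out <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ny <- length(years)
    mat <- p$baseline_mat + ifelse(late, p$mat_change, 0) +
      stats::rnorm(ny, 0, config$climate_noise_sd)
    precip <- p$baseline_precip + ifelse(late, p$precip_change, 0) +
      stats::rnorm(ny, 0, config$climate_noise_sd)
    cwd_y <- pmax(0, p$baseline_cwd + ifelse(late, p$cwd_change, 0) +
                    stats::rnorm(ny, 0, config$climate_noise_sd))
    aet <- matrix(50, ny, 12)
    pet <- aet
    pet[, 1:6] <- aet[, 1:6] - 20              # surplus months clamp to zero
    pet[, 7:12] <- aet[, 7:12] + cwd_y / 6     # deficit months carry the CWD
    df <- data.frame(plot_id = p$plot_id, year = years, mat = mat, precip = precip)
    colnames(pet) <- paste0("pet_m", 1:12)
    colnames(aet) <- paste0("aet_m", 1:12)
    cbind(df, pet, aet)
  })
  do.call(rbind, out)
}

#' Run every generator stage and optionally write the CSV artifacts
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes landscape.csv,
#'   species.csv, trees.csv, seedlings.csv, occurrences.csv and climate.csv
#'   (missing DBH encoded as empty fields).
#' @param n_occurrences occurrences per species for the niche-estimation
#'   input.
#' @param census_year first-census calendar year for the climate series.
#' @return list: config, landscape, species, trees, seedlings, occurrences,
#'   climate.
#' @export
simulate_inventory <- function(config = simulation_config(), dir = NULL,
                               n_occurrences = 500, census_year = 2005L) {
  validate_simulation_config(config)
  landscape <- generate_landscape(config)
  species <- generate_species_pool(config)
  census <- generate_tree_censuses(landscape, species, config)
  grid <- seq(config$mat_min - 3 * config$niche_breadth,
              config$mat_min + config$mat_gradient + 3 * config$niche_breadth,
              by = 0.05)
  occurrences <- generate_occurrences(species, grid, n_occurrences,
                                      seed = config$seed + 4000L)
  climate <- generate_climate_series(landscape, config, census_year)
  sim <- list(config = config, landscape = landscape, species = species,
              trees = census$trees, seedlings = census$seedlings,
              occurrences = occurrences, climate = climate)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(landscape, file.path(dir, "landscape.csv"), row.names = FALSE)
    utils::write.csv(species, file.path(dir, "species.csv"), row.names = FALSE)
    utils::write.csv(census$trees, file.path(dir, "trees.csv"), row.names = FALSE, na = "")
    utils::write.csv(census$seedlings, file.path(dir, "seedlings.csv"), row.names = FALSE)
    utils::write.csv(occurrences, file.path(dir, "occurrences.csv"), row.names = FALSE)
    utils::write.csv(climate, file.path(dir, "climate.csv"), row.names = FALSE)
  }
  sim
}
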