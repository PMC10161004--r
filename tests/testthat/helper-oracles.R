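# Independent oracles and random fixtures for property-style tests. These
# deliberately re-derive quantities through a different code path than the
# package (per-species aggregation, explicit fate subsetting) so agreement is
# a real cross-check.

# per-species basal-area-weighted mean (package computes per individual)
oracle_cti <- function(species, dbh, indices) {
  if (length(species) == 0L) return(NA_real_)
  ba <- tapply(pi * (dbh / 2)^2, species, sum)
  sum(ba * indices[names(ba)]) / sum(ba)
}

# independent reconstruction of the counterfactual T2 species/size lists
oracle_scenario_community <- function(trees, scenario) {
  surv <- subset(trees, fate == "survivor")
  died <- subset(trees, fate == "died")
  rec <- subset(trees, fate == "recruit")
  if (scenario == "all") {
    list(species = c(surv$species_id, rec$species_id),
         dbh = c(surv$dbh_t2_cm, rec$dbh_t2_cm))
  } else if (scenario == "mortality") {
    list(species = surv$species_id, dbh = surv$dbh_t1_cm)
  } else if (scenario == "growth") {
    list(species = c(surv$species_id, died$species_id),
         dbh = c(surv$dbh_t2_cm, died$dbh_t1_cm))
  } else if (scenario == "recruitment") {
    list(species = c(surv$species_id, died$species_id, rec$species_id),
         dbh = c(surv$dbh_t1_cm, died$dbh_t1_cm, rec$dbh_t2_cm))
  } else stop("unknown scenario")
}

oracle_decompose <- function(trees, indices) {
  t1 <- subset(trees, fate %in% c("survivor", "died"))
  cti1 <- oracle_cti(t1$species_id, t1$dbh_t1_cm, indices)
  comp <- sapply(c("all", "mortality", "growth", "recruitment"), function(sc) {
    cm <- oracle_scenario_community(trees, sc)
    oracle_cti(cm$species, cm$dbh, indices) - cti1
  })
  names(comp) <- c("delta_total", "delta_mortality", "delta_growth",
                   "delta_recruitment")
  comp
}

# random subplot of <= max_trees trees with arbitrary fates and sizes
random_subplot <- function(n_species = 5, max_trees = 10,
                           p_die = 0.25, p_recruit = 0.2,
                           zero_growth = FALSE) {
  n <- sample.int(max_trees, 1L)
  fate <- sample(c("survivor", "died", "recruit"), n, replace = TRUE,
                 prob = c(1 - p_die - p_recruit, p_die, p_recruit))
  dbh1 <- ifelse(fate == "recruit", NA_real_, runif(n, 12.7, 60))
  growth <- if (zero_growth) 0 else runif(n, -2, 8)  # negative growth allowed
  dbh2 <- ifelse(fate == "died", NA_real_,
                 ifelse(fate == "recruit", runif(n, 12.7, 15),
                        pmax(12.7, dbh1 + growth)))
  data.frame(tree_id = seq_len(n), plot_id = 1L, subplot_id = 1L,
             species_id = sample(paste0("s", seq_len(n_species)), n, TRUE),
             dbh_t1_cm = dbh1, dbh_t2_cm = dbh2,
             dist_m = runif(n, 0, 7.32), fate = fate, size_class = "main")
}

random_indices <- function(n_species = 5) {
  stats::setNames(runif(n_species, 2, 18), paste0("s", seq_len(n_species)))
}

# minimal hand-built landscape for covariate tests
tiny_landscape <- function(n_plots = 4, n_sub = 2) {
  idx <- rep(seq_len(n_plots), each = n_sub)
  set.seed(42)
  data.frame(plot_id = idx, subplot_id = rep(seq_len(n_sub), n_plots),
             x_km = idx * 10, y_km = idx * 5,
             latitude = 40 + idx / 10, slope = runif(n_plots * n_sub, 0, 30),
             aspect = runif(n_plots * n_sub, 0, 359.9),
             baseline_mat = rnorm(n_plots * n_sub, 10)[idx],
             baseline_precip = rnorm(n_plots, 800, 100)[idx],
             baseline_cwd = rnorm(n_plots, 300, 50)[idx],
             mat_change = rnorm(n_plots, 0.3, 0.1)[idx],
             precip_change = rnorm(n_plots, -10, 5)[idx],
             cwd_change = rnorm(n_plots, 5, 3)[idx],
             fire = c(TRUE, rep(FALSE, n_plots * n_sub - 1L)),
             insect = rep(c(TRUE, FALSE), length.out = n_plots * n_sub))
}
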