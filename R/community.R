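# Community temperature indices and the counterfactual demographic
# decomposition of their change, plus census filters, conifer fraction,
# sapling-class CTI and recruit-origin classification.

#' Basal area of a stem
#'
#' @param dbh diameter at breast height, cm (> 0).
#' @return cross-sectional area pi * (dbh/2)^2, cm^2.
#' @export
basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive and finite", call. = FALSE)
  }
  pi * (dbh / 2)^2
}

#' Filter trees to the census sampling frame
#'
#' Keeps main-class trees within `max_dist` of the subplot center (inclusive)
#' whose DBH meets the census threshold (inclusive) at the relevant timepoint.
#' The threshold is applied per timepoint: a tree below `min_dbh` at the first
#' census that crosses it by the second is reclassified as a recruit (its T1
#' record is not part of the censused community). Sapling-class rows keep only
#' the distance filter; their 2.5-12.7 cm bounds are validated by
#' [validate_inputs()], not enforced here.
#'
#' @param trees TreeRecord data.frame (columns as written by the generator).
#' @param min_dbh census DBH threshold, cm.
#' @param max_dist maximum distance from subplot center, m.
#' @return filtered (possibly empty) trees data.frame.
#' @export
filter_census_trees <- function(trees, min_dbh = 12.7, max_dist = 7.32) {
  if (nrow(trees) == 0L) return(trees)
  keep_dist <- !is.na(trees$dist_m) & trees$dist_m <= max_dist
  main <- trees$size_class == "main"
  t1_ok <- !is.na(trees$dbh_t1_cm) & trees$dbh_t1_cm >= min_dbh
  t2_ok <- !is.na(trees$dbh_t2_cm) & trees$dbh_t2_cm >= min_dbh
  # survivors below threshold at T1 but at/above it at T2 enter as recruits
  cross <- main & trees$fate == "survivor" & !t1_ok & t2_ok
  trees$fate[cross] <- "recruit"
  trees$dbh_t1_cm[cross] <- NA_real_
  rel_ok <- ifelse(trees$fate == "recruit", t2_ok, t1_ok)
  keep <- keep_dist & (!main | rel_ok)
  trees[keep, , drop = FALSE]
}

# trees present at one timepoint with their effective DBH
present_at <- function(trees, timepoint) {
  if (timepoint == "t1") {
    sel <- trees$fate %in% c("survivor", "died") & !is.na(trees$dbh_t1_cm)
    dbh <- trees$dbh_t1_cm
  } else {
    sel <- trees$fate %in% c("survivor", "recruit") & !is.na(trees$dbh_t2_cm)
    dbh <- trees$dbh_t2_cm
  }
  data.frame(species_id = trees$species_id[sel], dbh = dbh[sel])
}

#' Basal-area-weighted community temperature index
#'
#' Mean species temperature index across the trees present at one timepoint,
#' weighted by basal area: sum(BA_s * index_s) / sum(BA_s) with BA summed
#' over individuals of each species (equivalently computed per individual).
#'
#' @param trees TreeRecord data.frame for one subplot (any size classes; all
#'   rows are used — pre-filter with `size_class` or [filter_census_trees()]
#'   as appropriate).
#' @param indices named numeric vector species_id -> index (degC); see
#'   [index_vector()].
#' @param timepoint "t1" or "t2".
#' @return CTI in degrees C, or NA_real_ when the community is empty (zero
#'   total basal area) — an undefined-CTI signal, not an error.
#' @export
community_temperature_index <- function(trees, indices, timepoint = c("t1", "t2")) {
  timepoint <- match.arg(timepoint)
  comm <- present_at(trees, timepoint)
  if (nrow(comm) == 0L) return(NA_real_)
  miss <- setdiff(unique(comm$species_id), names(indices))
  if (length(miss) > 0L) {
    stop("no temperature index for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ba <- basal_area(comm$dbh)
  sum(ba * indices[comm$species_id]) / sum(ba)
}

#' Counterfactual second-census community for one demographic scenario
#'
#' Rebuilds the T2 community of a subplot under one of four scenarios,
#' isolating each demographic process:
#' * `all`: observed T2 (survivors at T2 size, recruits included, died
#'   removed);
#' * `mortality`: died removed; survivors held at T1 size; recruits omitted;
#' * `growth`: survivors at observed T2 size; died retained at T1 size;
#'   recruits omitted;
#' * `recruitment`: recruits at observed size; survivors and died retained at
#'   T1 size.
#'
#' @param trees TreeRecord data.frame for one subplot.
#' @param scenario one of "all", "mortality", "growth", "recruitment".
#' @return TreeRecord-shaped data.frame whose `dbh_t2_cm` holds the
#'   counterfactual T2 size and whose `fate` marks every retained T1 tree as
#'   "survivor", so [community_temperature_index()] at "t2" evaluates the
#'   counterfactual community directly.
#' @export
counterfactual_t2 <- function(trees, scenario = c("all", "mortality", "growth",
                                                  "recruitment")) {
  scenario <- match.arg(scenario)
  surv <- trees$fate == "survivor"
  died <- trees$fate == "died"
  rec <- trees$fate == "recruit"
  out <- switch(scenario,
    all = trees[surv | rec, , drop = FALSE],
    mortality = {
      x <- trees[surv, , drop = FALSE]
      x$dbh_t2_cm <- x$dbh_t1_cm
      x
    },
    growth = {
      x <- trees[surv | died, , drop = FALSE]
      d <- x$fate == "died"
      x$dbh_t2_cm[d] <- x$dbh_t1_cm[d]
      x$fate[d] <- "survivor"
      x
    },
    recruitment = {
      x <- trees[surv | died | rec, , drop = FALSE]
      t1 <- x$fate %in% c("survivor", "died")
      x$dbh_t2_cm[t1] <- x$dbh_t1_cm[t1]
      x$fate[x$fate == "died"] <- "survivor"
      x
    }
  )
  rownames(out) <- NULL
  out
}

#' Decompose one subplot's CTI change into demographic components
#'
#' For each scenario X, delta_X = CTI(counterfactual T2 under X) - CTI(T1).
#' The components need not sum to delta_total: basal-area weights make the
#' CTI nonlinear in the demographic processes.
#'
#' @param trees TreeRecord data.frame for one subplot (main size class).
#' @param indices named numeric vector species_id -> index (degC).
#' @return one-row data.frame: cti_t1, delta_total, delta_mortality,
#'   delta_growth, delta_recruitment, undefined (comma-separated component
#'   names whose counterfactual CTI was undefined, "" if none). cti_t1 is NA
#'   when the baseline community is empty; callers should then exclude the
#'   subplot.
#' @export
decompose_subplot <- function(trees, indices) {
  cti1 <- community_temperature_index(trees, indices, "t1")
  comp <- c(total = "all", mortality = "mortality", growth = "growth",
            recruitment = "recruitment")
  vals <- vapply(comp, function(sc) {
    community_temperature_index(counterfactual_t2(trees, sc), indices, "t2")
  }, numeric(1))
  undef <- names(comp)[is.na(vals)]
  data.frame(cti_t1 = cti1,
             delta_total = vals[["total"]] - cti1,
             delta_mortality = vals[["mortality"]] - cti1,
             delta_growth = vals[["growth"]] - cti1,
             delta_recruitment = vals[["recruitment"]] - cti1,
             undefined = paste(undef, collapse = ","))
}

#' Decompose CTI change for every subplot of a census table
#'
#' @param trees TreeRecord data.frame (main size class only is used).
#' @param indices named numeric vector species_id -> index (degC).
#' @return data.frame with plot_id, subplot_id and the [decompose_subplot()]
#'   columns; subplots with undefined baseline CTI are excluded, with their
#'   count in attribute "dropped".
#' @export
decompose <- function(trees, indices) {
  main <- trees[trees$size_class == "main", , drop = FALSE]
  key <- interaction(main$plot_id, main$subplot_id, drop = TRUE)
  pieces <- lapply(split(main, key), function(sub) {
    cbind(plot_id = sub$plot_id[1], subplot_id = sub$subplot_id[1],
          decompose_subplot(sub, indices))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  dropped <- sum(is.na(out$cti_t1))
  out <- out[!is.na(out$cti_t1), , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Baseline conifer fraction of basal area
#'
#' @param trees TreeRecord data.frame for one subplot.
#' @param conifer_flags named logical vector species_id -> conifer status.
#' @return conifer share of T1 basal area in [0, 1], or NA_real_ when the
#'   baseline community is empty.
#' @export
conifer_basal_fraction <- function(trees, conifer_flags) {
  comm <- present_at(trees, "t1")
  if (nrow(comm) == 0L) return(NA_real_)
  miss <- setdiff(unique(comm$species_id), names(conifer_flags))
  if (length(miss) > 0L) {
    stop("no conifer flag for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ba <- basal_area(comm$dbh)
  sum(ba[conifer_flags[comm$species_id]]) / sum(ba)
}

#' Classify the baseline origin of a new recruit
#'
#' A recruit into the main size class was either already present as a
#' conspecific sapling in the subplot's baseline sapling census, or (failing
#' that) represented by at least one conspecific baseline seedling tally, or
#' had likely not yet germinated at the baseline census.
#'
#' @param recruit one TreeRecord row with fate "recruit".
#' @param saplings baseline sapling TreeRecord rows (size_class "sapling",
#'   dbh_t1_cm present) for any subplots.
#' @param seedlings seedling tally data.frame (plot_id, subplot_id,
#'   species_id, count).
#' @return "sapling", "seedling" or "not_germinated".
#' @export
classify_recruit_origin <- function(recruit, saplings, seedlings) {
  if (recruit$fate != "recruit") stop("not a recruit record", call. = FALSE)
  sap <- saplings$size_class == "sapling" &
    saplings$plot_id == recruit$plot_id &
    saplings$subplot_id == recruit$subplot_id &
    saplings$species_id == recruit$species_id &
    !is.na(saplings$dbh_t1_cm)
  if (any(sap)) return("sapling")
  sd <- seedlings$plot_id == recruit$plot_id &
    seedlings$subplot_id == recruit$subplot_id &
    seedlings$species_id == recruit$species_id &
    seedlings$count > 0
  if (any(sd)) return("seedling")
  "not_germinated"
}

#' Sapling-class community temperature index
#'
#' [community_temperature_index()] restricted to the 2.5-12.7 cm sapling
#' class; main-class trees never contribute.
#'
#' @inheritParams community_temperature_index
#' @return CTI in degrees C, or NA_real_ if the subplot has no saplings at
#'   that timepoint.
#' @export
sapling_cti <- function(trees, indices, timepoint = c("t1", "t2")) {
  timepoint <- match.arg(timepoint)
  saps <- trees[trees$size_class == "sapling", , drop = FALSE]
  community_temperature_index(saps, indices, timepoint)
}

#' CTI table across subplots, timepoints and response variants
#'
#' Builds the long CTI table consumed by the regression stage: for each
#' subplot, the baseline CTI and the T2 CTI under each counterfactual variant
#' ("all", "mortality", "growth", "recruitment"), plus the sapling-class CTI
#' at both timepoints as the "sapling" variant. The T1 value is shared by the
#' four main-class variants; only the T2 response differs.
#'
#' @param trees TreeRecord data.frame.
#' @param indices named numeric vector species_id -> index (degC).
#' @return data.frame: plot_id, subplot_id, timepoint ("t1"/"t2"), variant,
#'   cti_degC (NA when undefined).
#' @export
cti_table <- function(trees, indices) {
  key <- interaction(trees$plot_id, trees$subplot_id, drop = TRUE)
  variants <- c("all", "mortality", "growth", "recruitment")
  pieces <- lapply(split(trees, key), function(sub) {
    main <- sub[sub$size_class == "main", , drop = FALSE]
    cti1 <- community_temperature_index(main, indices, "t1")
    rows <- lapply(variants, function(v) {
      data.frame(plot_id = sub$plot_id[1], subplot_id = sub$subplot_id[1],
                 timepoint = c("t1", "t2"), variant = v,
                 cti_degC = c(cti1,
                              community_temperature_index(
                                counterfactual_t2(main, v), indices, "t2")))
    })
    sap <- data.frame(plot_id = sub$plot_id[1], subplot_id = sub$subplot_id[1],
                      timepoint = c("t1", "t2"), variant = "sapling",
                      cti_degC = c(sapling_cti(sub, indices, "t1"),
                                   sapling_cti(sub, indices, "t2")))
    do.call(rbind, c(rows, list(sap)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
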