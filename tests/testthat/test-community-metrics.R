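test_that("basal area follows the circle formula and scaling law", {
  expect_equal(basal_area(12.7), pi * 6.35^2)
  expect_equal(basal_area(2), pi)
  expect_equal(basal_area(20) / basal_area(10), 4)
  expect_error(basal_area(0), "positive")
  expect_error(basal_area(-3), "positive")
})

test_that("census filter applies inclusive boundaries per timepoint", {
  trees <- data.frame(
    tree_id = 1:5, plot_id = 1, subplot_id = 1,
    species_id = "s1",
    dbh_t1_cm = c(12.7, 30, 12.0, 11.0, NA),
    dbh_t2_cm = c(13.0, 31, 13.5, 11.5, 14.0),
    dist_m = c(7.32, 7.33, 3, 3, 3),
    fate = c("survivor", "survivor", "survivor", "survivor", "recruit"),
    size_class = "main")
  out <- filter_census_trees(trees)
  expect_true(1 %in% out$tree_id)      # dbh 12.7 at dist 7.32: inclusive
  expect_false(2 %in% out$tree_id)     # dist 7.33 m excluded
  # below threshold at T1 but above at T2: reclassified as recruit
  expect_equal(out$fate[out$tree_id == 3], "recruit")
  expect_true(is.na(out$dbh_t1_cm[out$tree_id == 3]))
  expect_false(4 %in% out$tree_id)     # below threshold at both censuses
  expect_true(5 %in% out$tree_id)
  expect_equal(nrow(filter_census_trees(trees[0, ])), 0L)
})

test_that("CTI is the basal-area-weighted index mean", {
  idx <- c(A = 5, B = 10)
  one <- data.frame(tree_id = 1:3, plot_id = 1, subplot_id = 1,
                    species_id = "A", dbh_t1_cm = c(15, 20, 40),
                    dbh_t2_cm = c(16, 21, 41), dist_m = 1,
                    fate = "survivor", size_class = "main")
  expect_equal(community_temperature_index(one, idx, "t1"), 5)
  # BA ratio 1:3 across species -> 0.25*5 + 0.75*10 = 8.75
  two <- data.frame(tree_id = 1:2, plot_id = 1, subplot_id = 1,
                    species_id = c("A", "B"),
                    dbh_t1_cm = c(2, 2 * sqrt(3)) * 10,
                    dbh_t2_cm = c(21, 35), dist_m = 1,
                    fate = "survivor", size_class = "main")
  expect_equal(community_temperature_index(two, idx, "t1"), 8.75)
  expect_error(community_temperature_index(
    transform(one, species_id = "Z"), idx, "t1"), "Z")
  expect_true(is.na(community_temperature_index(one[0, ], idx, "t1")))
})

test_that("CTI matches the per-species brute-force oracle on random communities", {
  set.seed(10)
  for (i in 1:200) {
    sub <- random_subplot()
    idx <- random_indices()
    got <- community_temperature_index(sub, idx, "t1")
    t1 <- subset(sub, fate %in% c("survivor", "died"))
    want <- oracle_cti(t1$species_id, t1$dbh_t1_cm, idx)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("CTI respects convexity and split-tree invariance", {
  set.seed(11)
  for (i in 1:50) {
    sub <- random_subplot(p_recruit = 0)
    if (!any(sub$fate %in% c("survivor", "died"))) next
    idx <- random_indices()
    cti <- community_temperature_index(sub, idx, "t1")
    present <- unique(sub$species_id[sub$fate != "recruit"])
    expect_gte(cti, min(idx[present]) - 1e-12)
    expect_lte(cti, max(idx[present]) + 1e-12)
    # split the first tree into two of equal total basal area
    t <- sub[1, ]
    half <- t
    half$dbh_t1_cm <- t$dbh_t1_cm / sqrt(2)
    split_sub <- rbind(half, half, sub[-1, ])
    expect_equal(community_temperature_index(split_sub, idx, "t1"), cti,
                 tolerance = 1e-12)
  }
})

test_that("counterfactual communities follow the scenario rules", {
  # toy community: one dies, three grow, one recruits
  toy <- data.frame(
    tree_id = 1:5, plot_id = 1, subplot_id = 1,
    species_id = c("A", "A", "B", "B", "A"),
    dbh_t1_cm = c(20, 25, 30, 35, NA),
    dbh_t2_cm = c(NA, 28, 33, 38, 13),
    dist_m = 2,
    fate = c("died", "survivor", "survivor", "survivor", "recruit"),
    size_class = "main")
  mort <- counterfactual_t2(toy, "mortality")
  expect_equal(nrow(mort), 3L)                       # survivors only
  expect_equal(mort$dbh_t2_cm, mort$dbh_t1_cm)       # held at T1 size
  grow <- counterfactual_t2(toy, "growth")
  expect_equal(nrow(grow), 4L)                       # died kept, no recruit
  expect_equal(grow$dbh_t2_cm[grow$tree_id == 1], 20)
  expect_equal(grow$dbh_t2_cm[grow$tree_id == 2], 28)
  recr <- counterfactual_t2(toy, "recruitment")
  expect_equal(nrow(recr), 5L)                       # T1 count + recruits
  expect_true(all(recr$dbh_t2_cm[recr$tree_id != 5] ==
                    recr$dbh_t1_cm[recr$tree_id != 5]))
  expect_equal(recr$dbh_t2_cm[recr$tree_id == 5], 13)
  allc <- counterfactual_t2(toy, "all")
  expect_equal(sort(allc$tree_id), c(2, 3, 4, 5))
  expect_error(counterfactual_t2(toy, "pruning"))
})

test_that("with no demographic change every scenario reproduces T1", {
  static <- data.frame(tree_id = 1:4, plot_id = 1, subplot_id = 1,
                       species_id = c("A", "B", "A", "B"),
                       dbh_t1_cm = c(20, 25, 30, 35),
                       dbh_t2_cm = c(20, 25, 30, 35), dist_m = 2,
                       fate = "survivor", size_class = "main")
  idx <- c(A = 6, B = 12)
  cti1 <- community_temperature_index(static, idx, "t1")
  for (sc in c("all", "mortality", "growth", "recruitment")) {
    expect_equal(community_temperature_index(counterfactual_t2(static, sc),
                                             idx, "t2"), cti1)
  }
})

test_that("decomposition matches the independent oracle on random subplots", {
  set.seed(12)
  for (i in 1:300) {
    sub <- random_subplot()
    idx <- random_indices()
    if (!any(sub$fate %in% c("survivor", "died"))) next
    got <- decompose_subplot(sub, idx)
    want <- oracle_decompose(sub, idx)
    for (comp in names(want)) {
      if (is.na(want[[comp]])) {
        expect_true(is.na(got[[comp]]) ||
                      grepl(sub("delta_", "", comp), got$undefined))
      } else {
        # deltas are differences of two ~10 degC weighted means computed by
        # different summation orders, so compare on the CTI scale: absolute
        # agreement to 1e-10 degC
        expect_lt(abs(got[[comp]] - unname(want[[comp]])), 1e-10)
      }
    }
  }
})

test_that("single-process subplots collapse the decomposition identities", {
  idx <- c(A = 5, B = 15)
  # mortality only: component equals total exactly, others zero
  mort_only <- data.frame(tree_id = 1:3, plot_id = 1, subplot_id = 1,
                          species_id = c("A", "B", "B"),
                          dbh_t1_cm = c(20, 25, 30),
                          dbh_t2_cm = c(NA, 25, 30), dist_m = 1,
                          fate = c("died", "survivor", "survivor"),
                          size_class = "main")
  d <- decompose_subplot(mort_only, idx)
  expect_identical(d$delta_mortality, d$delta_total)
  expect_identical(d$delta_growth, 0)
  expect_identical(d$delta_recruitment, 0)
  # killing the coolest species raises the weighted mean
  expect_gt(d$delta_mortality, 0)
})

test_that("conifer basal fraction covers the boundary cases", {
  flags <- c(A = TRUE, B = FALSE)
  mk <- function(sp, dbh) data.frame(tree_id = seq_along(sp), plot_id = 1,
                                     subplot_id = 1, species_id = sp,
                                     dbh_t1_cm = dbh, dbh_t2_cm = dbh,
                                     dist_m = 1, fate = "survivor",
                                     size_class = "main")
  expect_equal(conifer_basal_fraction(mk(c("A", "A"), c(20, 30)), flags), 1)
  expect_equal(conifer_basal_fraction(mk(c("B", "B"), c(20, 30)), flags), 0)
  # conifer BA 1 : broadleaf BA 3 -> 0.25
  expect_equal(conifer_basal_fraction(mk(c("A", "B"), c(20, 20 * sqrt(3))),
                                      flags), 0.25)
  expect_true(is.na(conifer_basal_fraction(mk("A", 20)[0, ], flags)))
})

test_that("recruit origin classification follows the sapling/seedling rules", {
  recruit <- data.frame(tree_id = 1, plot_id = 1, subplot_id = 2,
                        species_id = "A", dbh_t1_cm = NA, dbh_t2_cm = 13,
                        dist_m = 1, fate = "recruit", size_class = "main")
  saplings <- data.frame(tree_id = 2, plot_id = 1, subplot_id = 2,
                         species_id = "A", dbh_t1_cm = 8, dbh_t2_cm = NA,
                         dist_m = 1, fate = "died", size_class = "sapling")
  seedlings <- data.frame(plot_id = 1, subplot_id = 2, species_id = "A",
                          count = 2L)
  none <- seedlings[0, ]
  expect_equal(classify_recruit_origin(recruit, saplings, none), "sapling")
  expect_equal(classify_recruit_origin(recruit, saplings[0, ], seedlings),
               "seedling")
  expect_equal(classify_recruit_origin(recruit, saplings[0, ], none),
               "not_germinated")
  # conspecific match is required
  other <- transform(saplings, species_id = "B")
  expect_equal(classify_recruit_origin(recruit, other, none), "not_germinated")
  expect_error(classify_recruit_origin(transform(recruit, fate = "survivor"),
                                       saplings, none), "not a recruit")
})

test_that("sapling CTI ignores main-class trees", {
  idx <- c(A = 5, B = 15)
  mixed <- data.frame(tree_id = 1:3, plot_id = 1, subplot_id = 1,
                      species_id = c("A", "B", "B"),
                      dbh_t1_cm = c(6, 40, 9), dbh_t2_cm = c(7, 41, 10),
                      dist_m = 1, fate = "survivor",
                      size_class = c("sapling", "main", "sapling"))
  only_sap <- mixed[mixed$size_class == "sapling", ]
  expect_equal(sapling_cti(mixed, idx, "t1"),
               community_temperature_index(only_sap, idx, "t1"))
  expect_equal(sapling_cti(mixed[1, ], idx, "t1"), 5)
  expect_true(is.na(sapling_cti(mixed[2, ], idx, "t1")))
})
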