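# Adult pools, quadrant dispersal, fecundity-weighted mating, oviposition.

test_that("survivors map to quadrant pools with exact conservation", {
  # empty lattice -> empty pools
  lat <- lattice_from_matrix(matrix(NA_character_, 6, 6))
  expect_equal(sum(survivors_to_pools(lat)), 0)

  # all survivors in the top-left quadrant
  keys <- matrix(NA_character_, 6, 6)
  keys[1:3, 1:3] <- "HA-RS"
  pools <- survivors_to_pools(lattice_from_matrix(keys))
  expect_equal(sum(pools["A", , ]), 9)
  expect_equal(sum(pools[c("B", "C", "D"), , ]), 0)

  set.seed(17)
  lat <- init_lattice(21, 21, occupancy = 0.4)
  pools <- survivors_to_pools(lat)
  expect_equal(sum(pools), sum(lat$grid > 0))
  # per-strain totals agree with the lattice census
  cnt <- lattice_counts(lat)
  expect_equal(apply(pools, 2:3, sum)["SF", ], cnt$SF)
  expect_equal(apply(pools, 2:3, sum)["HA", ], cnt$HA)
})

test_that("dispersal conserves adults exactly and follows 50/25/25", {
  keys <- matrix(NA_character_, 10, 10)
  keys[1:5, 1:5] <- "SF-SS"
  pools <- survivors_to_pools(lattice_from_matrix(keys))
  pools["A", "SF", "SS"] <- 1000L
  set.seed(23)
  for (i in 1:20) {
    out <- disperse(pools)
    expect_identical(sum(out), sum(pools))
  }
  out <- disperse(pools)
  # A's neighbors in the 2x2 layout are B and C; D receives nothing
  expect_equal(out["D", "SF", "SS"], 0)
  stays <- replicate(60, disperse(pools)["A", "SF", "SS"])
  sd3 <- 3 * sqrt(1000 * 0.5 * 0.5)
  expect_lt(abs(mean(stays) - 500), sd3 / sqrt(60) * 3 + 5)
  expect_true(all(abs(stays - 500) < 3.5 * sqrt(1000 * 0.25)))
  # zero adults -> no movement
  pools["A", "SF", "SS"] <- 0L
  expect_equal(sum(disperse(pools)), 0)
  bad <- default_quadrant_scheme(); bad$stay <- 0.6
  expect_error(disperse(pools, bad), "stay")
})

test_that("symmetric pools are stationary in expectation", {
  pools <- array(0L, dim = c(4, 2, 3),
                 dimnames = list(c("A", "B", "C", "D"), c("SF", "HA"),
                                 c("SS", "RS", "RR")))
  pools[, "SF", "SS"] <- 400L
  set.seed(29)
  totals <- sapply(1:200, function(i) disperse(pools)[, "SF", "SS"])
  expect_true(all(abs(rowMeans(totals) - 400) < 3 * sqrt(400 * 0.5) /
                    sqrt(200) * 3 + 2))
})

test_that("reproductive success applies the fecundity cost to RR", {
  ft <- default_fitness_table()
  pool <- matrix(0, 2, 3, dimnames = list(c("SF", "HA"),
                                          c("SS", "RS", "RR")))
  pool["SF", "SS"] <- 40
  expect_equal(reproductive_success(pool, ft, "corn"),
               c(SF = 40 * 1.0, HA = 0))
  pool["SF", "SS"] <- 0; pool["SF", "RR"] <- 40
  expect_equal(reproductive_success(pool, ft, "corn"),
               c(SF = 0.75 * 40 * 1.0, HA = 0))
  # the cost ratio is exactly 25% whatever the crop and species
  for (crop in c("cotton", "corn", "soybean")) for (sp in c("SF", "HA")) {
    p_ss <- matrix(0, 2, 3, dimnames = dimnames(pool)); p_ss[sp, "SS"] <- 10
    p_rr <- matrix(0, 2, 3, dimnames = dimnames(pool)); p_rr[sp, "RR"] <- 10
    expect_equal(reproductive_success(p_rr, ft, crop)[[sp]] /
                   reproductive_success(p_ss, ft, crop)[[sp]], 0.75)
  }
})

test_that("gametes are fecundity-weighted", {
  # equal SS and RR adults with a 25% RR cost: p_R = 0.75 / 1.75
  # (direct enumeration: each adult contributes gametes proportional to
  # its effective Ro; RR gametes all carry R, SS gametes none)
  dist <- refugeCA:::.mating_distribution(c(SS = 30, RS = 0, RR = 30),
                                          c(SS = 1, RS = 1, RR = 0.75))
  p_w <- 0.75 / 1.75
  expect_equal(dist, hw_genotype_frequencies(p_w))
  # zero-weight pool produces no offspring distribution
  expect_null(refugeCA:::.mating_distribution(c(SS = 0, RS = 0, RR = 5),
                                              c(SS = 1, RS = 1, RR = 0)))
})

test_that("occupation probability follows the fitness normalization", {
  ft <- default_fitness_table()
  pool <- matrix(0, 2, 3, dimnames = list(c("SF", "HA"),
                                          c("SS", "RS", "RR")))
  keys <- matrix(NA_character_, 3, 3)
  lat <- lattice_from_matrix(keys)
  v_empty <- neighborhood_view(lat, 2, 2)
  # no neighbors and empty pool -> W = 0
  expect_equal(occupation_probability(v_empty, pool, ft, "cotton"),
               c(SF = 0, HA = 0))
  # 8 neighbors of the max-fitness species (HA-SS on cotton) with an
  # all-SS pool -> W = 1
  keys[] <- "HA-SS"; keys[2, 2] <- NA
  v_full <- neighborhood_view(lattice_from_matrix(keys), 2, 2)
  pool["HA", "SS"] <- 50
  expect_equal(occupation_probability(v_full, pool, ft, "cotton"),
               c(SF = 0, HA = 1))
  # neighbors but an empty quadrant pool -> W = 0
  pool["HA", "SS"] <- 0
  expect_equal(occupation_probability(v_full, pool, ft, "cotton")[["HA"]], 0)
  # equal local pressure and equal fitness -> 50:50 lottery weights
  ft1 <- flat_fitness()
  keys <- matrix(NA_character_, 3, 3)
  keys[1, 1:2] <- "SF-SS"; keys[3, 1:2] <- "HA-SS"
  v <- neighborhood_view(lattice_from_matrix(keys), 2, 2)
  pool["SF", "SS"] <- 10; pool["HA", "SS"] <- 10
  w <- occupation_probability(v, pool, ft1, "corn")
  expect_equal(w[["SF"]], w[["HA"]])
  keys[2, 2] <- "SF-SS"
  expect_error(occupation_probability(
    neighborhood_view(lattice_from_matrix(keys), 2, 2), pool, ft, "cotton"),
    "empty cells")
})

test_that("reproduction phase never overwrites and keeps genotype closure", {
  set.seed(37)
  lat <- init_lattice(20, 20, occupancy = 0.5, species_mix = 1, p_R = 0)
  pools <- disperse(survivors_to_pools(lat))
  out <- reproduction_phase(lat, pools, default_fitness_table(), "corn")
  expect_equal(out$generation, lat$generation + 1L)
  # occupied cells unchanged
  occ <- lat$grid > 0
  expect_identical(out$grid[occ], lat$grid[occ])
  # monomorphic SS population only produces SS colonizers
  cnt <- lattice_counts(out)
  expect_equal(cnt$SF[["RS"]] + cnt$SF[["RR"]], 0)
  expect_gt(sum(out$grid > 0), sum(lat$grid > 0))  # some colonization
  # no adults anywhere -> lattice unchanged except the generation counter
  empty_pools <- survivors_to_pools(lattice_from_matrix(
    matrix(NA_character_, 20, 20)))
  out2 <- reproduction_phase(lat, empty_pools, default_fitness_table(),
                             "corn")
  expect_identical(out2$grid, lat$grid)
  expect_equal(out2$generation, lat$generation + 1L)
})

test_that("neutral settings make the allele frequency a martingale", {
  # equal payoffs, no fecundity cost: the mean trajectory over replicates
  # stays flat at the initial frequency within 3 standard errors
  payoffs <- neutral_payoffs(0.5, crop = "corn")
  ft <- flat_fitness(cost_RR = 0)
  cfg <- simulation_config("corn", "intra_plus_inter", "BH_00RR",
                           width = 30, height = 30, generations = 25,
                           replicates = 20, fitness = ft, p_R = 0.3,
                           seed = 97)
  res <- run_scenario(cfg, payoffs = payoffs)
  fin <- res$trajectory[res$trajectory$generation == 25 &
                          !is.na(res$trajectory$p_R), ]
  for (sp in c("SF", "HA")) {
    p <- fin$p_R[fin$species == sp]
    se <- stats::sd(p) / sqrt(length(p))
    expect_lt(abs(mean(p) - 0.3), 3 * se)
  }
})

test_that("a larger RR fecundity cost depresses the R frequency", {
  payoffs <- neutral_payoffs(0.5, crop = "corn", mode = "intra_only")
  final_p <- vapply(c(0, 0.25, 0.5), function(cost) {
    cfg <- simulation_config("corn", "intra_only", "BH_00RR", species = "SF",
                             width = 30, height = 30, generations = 30,
                             replicates = 12,
                             fitness = flat_fitness(cost_RR = cost),
                             p_R = 0.5, seed = 131)
    res <- run_scenario(cfg, payoffs = payoffs)
    fin <- res$trajectory[res$trajectory$generation == 30, ]
    mean(fin$p_R[fin$species == "SF"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(final_p) < 0))
})
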