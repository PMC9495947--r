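# Lattice engine: toroidal neighborhoods, encounter rule, stochastic
# survival, synchronous competition phase.

test_that("toroidal topology gives every cell 8 Moore neighbors", {
  keys <- matrix("SF-SS", 4, 5)
  lat <- lattice_from_matrix(keys)
  for (cell in list(c(1, 1), c(1, 5), c(4, 1), c(4, 5), c(2, 3))) {
    v <- neighborhood_view(lat, cell[1], cell[2])
    expect_length(v$neighbors, 8)
    expect_false(anyNA(v$neighbors))
  }
  # corner of a sparse lattice wraps to the opposite edges
  keys2 <- matrix(NA_character_, 3, 3)
  keys2[1, 1] <- "SF-SS"; keys2[3, 3] <- "HA-RR"
  lat2 <- lattice_from_matrix(keys2)
  v <- neighborhood_view(lat2, 1, 1)
  expect_identical(sort(v$neighbors[!is.na(v$neighbors)]), "HA-RR")
})

test_that("initialization realizes the configured frequencies", {
  set.seed(101)
  lat <- init_lattice(width = 100, height = 100, occupancy = 0.5,
                      species_mix = 0.5, p_R = 0.1)
  cnt <- lattice_counts(lat)
  n_occ <- sum(lat$grid > 0L)
  expect_equal(n_occ / 10000, 0.5, tolerance = 0.05)
  for (sp in c("SF", "HA")) {
    n <- sum(cnt[[sp]])
    p_hat <- allele_frequency(cnt[[sp]])
    se <- sqrt(0.1 * 0.9 / (2 * n))
    expect_lt(abs(p_hat - 0.1), 3 * se)
  }
  # boundary cases
  set.seed(1)
  expect_equal(sum(init_lattice(10, 10, occupancy = 0)$grid), 0)
  lat0 <- init_lattice(20, 20, p_R = 0)
  expect_equal(sum(lattice_counts(lat0)$SF[c("RS", "RR")]) +
                 sum(lattice_counts(lat0)$HA[c("RS", "RR")]), 0)
  expect_error(init_lattice(10, 10, occupancy = 1.5), "\\[0, 1\\]")
  expect_error(init_lattice(10, 10, p_R = -0.1), "\\[0, 1\\]")
})

test_that("encounter probability is the eligible window occupancy over 8", {
  keys <- matrix(NA_character_, 3, 3)
  keys[2, 2] <- "SF-SS"
  lat <- lattice_from_matrix(keys)
  v <- neighborhood_view(lat, 2, 2)
  expect_equal(encounter_probability(v, "intra_plus_inter"), 0)

  keys[] <- "HA-RR"; keys[2, 2] <- "SF-SS"
  v <- neighborhood_view(lattice_from_matrix(keys), 2, 2)
  expect_equal(encounter_probability(v, "intra_plus_inter"), 1)
  # in intra-only mode the 8 heterospecific neighbors are not competitors
  expect_equal(encounter_probability(v, "intra_only"), 0)

  keys <- matrix(NA_character_, 3, 3)
  keys[2, 2] <- "SF-SS"; keys[1, 1] <- "SF-RR"; keys[3, 3] <- "HA-SS"
  v <- neighborhood_view(lattice_from_matrix(keys), 2, 2)
  expect_equal(encounter_probability(v, "intra_plus_inter"), 0.25)
  expect_equal(encounter_probability(v, "intra_only"), 0.125)
  expect_error(encounter_probability(neighborhood_view(lat, 1, 1)), "empty")
})

test_that("draw_encounter samples opponents uniformly among individuals", {
  keys <- matrix(NA_character_, 3, 3)
  keys[2, 2] <- "SF-SS"
  lat <- lattice_from_matrix(keys)
  set.seed(5)
  expect_null(draw_encounter(neighborhood_view(lat, 2, 2)))

  keys[2, 1] <- "HA-SS"
  keys[1, 1:3] <- "SF-RR"  # three SF-RR among neighbors
  lat <- lattice_from_matrix(keys)
  v <- neighborhood_view(lat, 2, 2)
  expect_equal(encounter_probability(v, "intra_plus_inter"), 0.5)
  set.seed(9)
  draws <- replicate(4000, draw_encounter(v, "intra_plus_inter"))
  draws <- unlist(draws[!vapply(draws, is.null, logical(1))])
  # conditional on an encounter, SF-RR is drawn with probability 3/4
  expect_equal(mean(draws == "SF-RR"), 0.75, tolerance = 0.03)
})

test_that("survival resolution is Bernoulli in the payoff", {
  corn <- expand_heterozygotes(load_payoff_fixture("corn"), "BH_00RR")
  set.seed(3)
  # printed 0.00: certain death
  expect_false(any(replicate(200, resolve_survival("HA-SS", "SF-RR", corn))))
  cotton <- expand_heterozygotes(load_payoff_fixture("cotton"), "BH_00RR")
  surv <- mean(replicate(10000,
                         resolve_survival("SF-SS", "HA-SS", cotton)))
  expect_equal(surv, 0.60, tolerance = 0.015)
})

test_that("competition phase is synchronous and never creates larvae", {
  payoffs <- neutral_payoffs(0)  # every encounter is lethal
  # a single larva has no competitors and always survives
  keys <- matrix(NA_character_, 5, 5)
  keys[3, 3] <- "SF-SS"
  lat <- lattice_from_matrix(keys)
  set.seed(2)
  expect_identical(competition_phase(lat, payoffs)$grid, lat$grid)

  # two adjacent larvae with mutual rho = 0: when both encounters fire,
  # BOTH die (each is resolved against the pre-update state)
  keys[3, 4] <- "SF-RR"
  lat2 <- lattice_from_matrix(keys)
  set.seed(7)
  died_together <- replicate(400, {
    out <- competition_phase(lat2, payoffs)
    sum(out$grid > 0)
  })
  # each larva independently encounters with probability 1/8
  expect_true(any(died_together == 0))
  expect_false(any(died_together > 2))

  # occupancy is non-increasing for any payoff matrix
  set.seed(21)
  lat3 <- init_lattice(30, 30, occupancy = 0.7)
  mixed <- expand_heterozygotes(load_payoff_fixture("corn"), "BH_50RR")
  for (i in 1:5) {
    out <- competition_phase(lat3, mixed)
    expect_lte(sum(out$grid > 0), sum(lat3$grid > 0))
    lat3 <- out
  }
})

test_that("survivor counts match a per-cell probability oracle", {
  # 5x5 fixed configuration: enumerate each larva's exact survival
  # probability (encounter prob x expected payoff over the uniform
  # opponent draw) and compare the Monte-Carlo mean survivor count
  set.seed(31)
  keys <- matrix(NA_character_, 5, 5)
  keys[sample(25, 12)] <- sample(names(refugeCA:::STRAIN_CODES), 12,
                                 replace = TRUE)
  lat <- lattice_from_matrix(keys)
  payoffs <- expand_heterozygotes(load_payoff_fixture("cotton"), "BH_50RR")

  expected <- 0
  for (r in 1:5) for (c in 1:5) {
    if (is.na(keys[r, c])) next
    v <- neighborhood_view(lat, r, c)
    nb <- v$neighbors[!is.na(v$neighbors)]
    p_enc <- length(nb) / 8
    if (length(nb) == 0) {
      expected <- expected + 1
    } else {
      mean_rho <- mean(vapply(nb, function(o)
        payoff_lookup(payoffs, v$focal, o), numeric(1)))
      expected <- expected + (1 - p_enc) + p_enc * mean_rho
    }
  }
  sims <- replicate(3000, sum(competition_phase(lat, payoffs)$grid > 0))
  se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected), 4 * se + 1e-9)
})

test_that("neutral payoffs leave survivor genotype composition unbiased", {
  payoffs <- neutral_payoffs(0.5)
  set.seed(41)
  lat <- init_lattice(40, 40, occupancy = 0.6, p_R = 0.3)
  pre <- lattice_counts(lat)
  pre_all <- pre$SF + pre$HA
  post_all <- c(SS = 0, RS = 0, RR = 0)
  for (i in 1:50) {
    out <- lattice_counts(competition_phase(lat, payoffs))
    post_all <- post_all + out$SF + out$HA
  }
  chi <- suppressWarnings(stats::chisq.test(post_all,
                                            p = pre_all / sum(pre_all)))
  expect_gt(chi$p.value, 0.001)
})

test_that("no R allele ever appears from a p_R = 0 start", {
  cfg <- simulation_config("corn", "intra_plus_inter", "BH_00RR",
                           width = 20, height = 20, generations = 15,
                           replicates = 2, p_R = 0, seed = 77)
  res <- run_scenario(cfg)
  expect_equal(sum(res$trajectory$n_RS) + sum(res$trajectory$n_RR), 0)
})
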