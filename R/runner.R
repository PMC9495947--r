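## Orchestration of simulation scenarios: one generation = competition ->
## adulthood -> quadrant dispersal -> mating/oviposition. Scenarios are
## replicated with independently seeded streams and summarized as
## allele-frequency trajectories per species.

#' Build a validated simulation configuration
#'
#' Defaults reproduce the headline study conditions: a 100 x 100 toroidal
#' lattice, 50 replicates of 100 generations, initial resistance-allele
#' frequency 0.1 with Hardy-Weinberg genotypes, initial occupancy 0.5
#' with a 50:50 species mix, and a 25% RR fecundity cost.
#'
#' @param crop `"cotton"`, `"corn"` or `"soybean"`.
#' @param mode `"intra_plus_inter"` (both species on one lattice, all
#'   encounters count) or `"intra_only"` (a single-species run; set
#'   `species`).
#' @param bh Heterozygote behavior scenario: `"BH_00RR"`, `"BH_50RR"` or
#'   `"BH_100RR"`.
#' @param species `"both"` (required for `intra_plus_inter`) or a single
#'   species `"SF"`/`"HA"` (required for `intra_only`).
#' @param width,height,generations,replicates Run dimensions.
#' @param p_R Initial resistance-allele frequency.
#' @param occupancy Initial occupied-cell fraction.
#' @param species_mix Fraction of occupied cells that are SF at
#'   initialization (ignored for single-species runs).
#' @param fitness Fitness table, see [default_fitness_table()].
#' @param scheme Quadrant dispersal scheme.
#' @param seed Master seed; each replicate derives its own stream from it.
#' @param allow_default_payoffs If `FALSE`, [run_scenario()] refuses
#'   payoff matrices containing gap-filled (`"default"`-provenance) cells.
#' @return A `sim_config` object.
#' @export
simulation_config <- function(crop, mode = c("intra_plus_inter", "intra_only"),
                              bh = HETEROZYGOTE_BEHAVIORS,
                              species = c("both", "SF", "HA"),
                              width = 100, height = 100,
                              generations = 100, replicates = 50,
                              p_R = 0.1, occupancy = 0.5, species_mix = 0.5,
                              fitness = default_fitness_table(),
                              scheme = default_quadrant_scheme(),
                              seed = 1L, allow_default_payoffs = TRUE) {
  crop <- match.arg(crop, CROPS)
  mode <- match.arg(mode)
  bh <- match.arg(bh)
  species <- match.arg(species)
  if (mode == "intra_only" && species == "both")
    stop("intra_only runs are single-species: set species = 'SF' or 'HA'",
         call. = FALSE)
  if (mode == "intra_plus_inter" && species != "both")
    stop("intra_plus_inter runs use both species", call. = FALSE)
  stopifnot(generations >= 1, replicates >= 1)
  if (occupancy < 0 || occupancy > 1 || p_R < 0 || p_R > 1)
    stop("'occupancy' and 'p_R' must lie in [0, 1]", call. = FALSE)
  .check_fitness(fitness, crop)
  .check_scheme(scheme)
  if (species == "SF") species_mix <- 1
  if (species == "HA") species_mix <- 0
  structure(list(crop = crop, mode = mode, bh = bh, species = species,
                 width = as.integer(width), height = as.integer(height),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 p_R = p_R, occupancy = occupancy, species_mix = species_mix,
                 fitness = fitness, scheme = scheme, seed = as.integer(seed),
                 allow_default_payoffs = isTRUE(allow_default_payoffs)),
            class = "sim_config")
}

#' Derive a replicate seed from the master seed
#'
#' Deterministic map keeping seeds below 2^31 so replicates are
#' independent streams and deleting one replicate never perturbs another.
#'
#' @param master Master seed (integer).
#' @param replicate Replicate index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(master, replicate) {
  as.integer(((master %% 1000003) * 20011 + replicate * 7919) %% 2147483629L)
}

#' Advance the simulation by one generation
#'
#' Applies, in order: the synchronous competition phase, the
#' survivor-to-adult transition into quadrant pools, quadrant dispersal,
#' and the reproduction phase (which increments the generation counter).
#'
#' @param lattice A `ca_lattice`.
#' @param payoffs An expanded `payoff_matrix`.
#' @param config A `sim_config`.
#' @return The next generation's `ca_lattice`.
#' @export
step_generation <- function(lattice, payoffs, config) {
  lattice <- competition_phase(lattice, payoffs)
  pools <- survivors_to_pools(lattice)
  pools <- disperse(pools, config$scheme)
  reproduction_phase(lattice, pools, config$fitness, config$crop)
}

.record_state <- function(lattice, replicate) {
  cnt <- lattice_counts(lattice)
  do.call(rbind, lapply(SPECIES, function(sp) {
    n <- cnt[[sp]]
    tot <- sum(n)
    data.frame(replicate = replicate, generation = lattice$generation,
               species = sp, n_SS = n[["SS"]], n_RS = n[["RS"]],
               n_RR = n[["RR"]],
               p_R = if (tot > 0) unname((2 * n[["RR"]] + n[["RS"]]) /
                                           (2 * tot)) else NA_real_,
               occupied = tot, extinct = tot == 0,
               stringsAsFactors = FALSE)
  }))
}

#' Run one scenario (replicated simulation)
#'
#' Runs `config$replicates` independent replicates of
#' `config$generations` generations each, with per-replicate seeds
#' derived from the master seed. Generation 0 (the initial state) is
#' recorded before any update, so a trajectory has `generations + 1`
#' rows per species. Once a species' lattice count reaches zero it is
#' extinct for good (there is no immigration), and its allele frequency
#' is missing thereafter.
#'
#' @param config A `sim_config`.
#' @param payoffs Optional pre-built expanded `payoff_matrix`; by default
#'   the shipped fixture for `config$crop` is loaded and expanded under
#'   `config$bh`.
#' @return A `scenario_result`: the config, the full per-replicate
#'   trajectory data frame (columns `replicate`, `generation`, `species`,
#'   `n_SS`, `n_RS`, `n_RR`, `p_R`, `occupied`, `extinct`), the
#'   per-generation summary (mean and 2.5-97.5% replicate envelope of
#'   `p_R` per species), and a per-replicate terminal-state
#'   classification.
#' @examples
#' cfg <- simulation_config("cotton", "intra_only", "BH_00RR", species = "SF",
#'                          width = 20, height = 20, generations = 5,
#'                          replicates = 2, seed = 42)
#' res <- run_scenario(cfg)
#' head(res$summary)
#' @export
run_scenario <- function(config, payoffs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(payoffs)) {
    payoffs <- load_payoff_fixture(config$crop, mode = config$mode)
    payoffs <- expand_heterozygotes(payoffs, config$bh)
  }
  if (is.na(payoffs$expanded))
    stop("payoffs must be heterozygote-expanded", call. = FALSE)
  if (payoffs$mode != config$mode)
    stop("payoff matrix mode (", payoffs$mode,
         ") does not match the config mode (", config$mode, ")",
         call. = FALSE)
  n_default <- sum(payoffs$entries$provenance == "default")
  if (n_default > 0 && !config$allow_default_payoffs)
    stop(n_default, " payoff cells are gap-filled defaults; set ",
         "allow_default_payoffs = TRUE to acknowledge", call. = FALSE)

  traj <- vector("list", config$replicates)
  for (rep_i in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, rep_i))
    lat <- init_lattice(config$width, config$height, config$occupancy,
                        config$species_mix, config$p_R)
    rows <- vector("list", config$generations + 1L)
    rows[[1]] <- .record_state(lat, rep_i)
    for (t in seq_len(config$generations)) {
      if (sum(lat$grid > 0L) == 0L) {
        ## total extinction: remaining steps are no-ops
        lat$generation <- lat$generation + 1L
      } else {
        lat <- step_generation(lat, payoffs, config)
      }
      rows[[t + 1L]] <- .record_state(lat, rep_i)
    }
    traj[[rep_i]] <- do.call(rbind, rows)
  }
  traj <- do.call(rbind, traj)
  rownames(traj) <- NULL
  structure(list(config = config,
                 payoff_provenance = table(payoffs$entries$provenance),
                 trajectory = traj,
                 summary = summarize_trajectory(traj),
                 terminal = classify_terminal(traj)),
            class = "scenario_result")
}

#' Summarize a trajectory data frame
#'
#' Per generation and species: the mean allele frequency over replicates
#' in which the species persists, the 2.5-97.5 percentile replicate
#' envelope (widened to include the mean if a skewed small sample would
#' otherwise leave it outside), and the number of surviving replicates.
#'
#' @param traj A trajectory data frame as produced by [run_scenario()].
#' @return A data frame with columns `generation`, `species`, `mean_p_R`,
#'   `env_lo`, `env_hi`, `n_alive`.
#' @export
summarize_trajectory <- function(traj) {
  out <- do.call(rbind, lapply(split(traj, list(traj$generation,
                                                traj$species)),
                               function(d) {
    p <- d$p_R[!is.na(d$p_R)]
    if (!length(p))
      return(data.frame(generation = d$generation[1], species = d$species[1],
                        mean_p_R = NA_real_, env_lo = NA_real_,
                        env_hi = NA_real_, n_alive = 0L))
    m <- mean(p)
    q <- stats::quantile(p, c(0.025, 0.975), names = FALSE)
    data.frame(generation = d$generation[1], species = d$species[1],
               mean_p_R = m, env_lo = min(q[1], m), env_hi = max(q[2], m),
               n_alive = length(p))
  }))
  out <- out[order(out$species, out$generation), ]
  rownames(out) <- NULL
  out
}

#' Classify the terminal state of each replicate
#'
#' Per replicate and species: `"extinct"` if the species died out,
#' `"fixation_R"` if the final resistance-allele frequency is 1,
#' `"fixation_S"` if it is 0, else `"polymorphic"`.
#'
#' @inheritParams summarize_trajectory
#' @return Data frame with columns `replicate`, `species`, `state`.
#' @export
classify_terminal <- function(traj) {
  final_gen <- max(traj$generation)
  fin <- traj[traj$generation == final_gen, ]
  data.frame(replicate = fin$replicate, species = fin$species,
             state = ifelse(fin$extinct, "extinct",
                            ifelse(fin$p_R >= 1, "fixation_R",
                                   ifelse(fin$p_R <= 0, "fixation_S",
                                          "polymorphic"))),
             stringsAsFactors = FALSE)
}

#' Scenario identifier string
#' @param config A `sim_config`.
#' @return e.g. `"cotton_intra_plus_inter_both_BH_00RR"`.
#' @export
scenario_id <- function(config) {
  paste(config$crop, config$mode, config$species, config$bh, sep = "_")
}

#' Configurations for the full study grid
#'
#' The full panel grid: 3 crops x (intraspecific-only for each species +
#' intra- plus interspecific) x 3 heterozygote behaviors = 27 scenarios.
#'
#' @param seed Master seed shared by all scenarios.
#' @param ... Further arguments passed to [simulation_config()] (e.g.
#'   `generations`, `replicates`, `width`).
#' @return List of `sim_config` objects.
#' @export
study_grid_configs <- function(seed = 1L, ...) {
  configs <- list()
  for (crop in CROPS) for (bh in HETEROZYGOTE_BEHAVIORS) {
    configs[[length(configs) + 1L]] <-
      simulation_config(crop, "intra_plus_inter", bh, species = "both",
                        seed = seed, ...)
    for (sp in SPECIES)
      configs[[length(configs) + 1L]] <-
        simulation_config(crop, "intra_only", bh, species = sp,
                          seed = seed, ...)
  }
  configs
}

#' Run a collection of scenarios and write their outputs
#'
#' Executes every scenario, writing one trajectory CSV and one summary
#' CSV per scenario plus a JSON manifest (config echo, seeds, payoff
#' provenance counts, package version). A failing scenario is reported in
#' the manifest; completed ones are retained.
#'
#' @param configs List of `sim_config` objects.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of `scenario_result` objects (or
#'   `try-error` for failures).
#' @export
run_grid <- function(configs, out_dir) {
  if (!length(configs)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(scenarios = list(),
                     package_version = as.character(
                       utils::packageVersion("refugeCA")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list()))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  entries <- list()
  for (config in configs) {
    sid <- scenario_id(config)
    res <- tryCatch(run_scenario(config), error = identity)
    results[[sid]] <- res
    if (inherits(res, "error")) {
      entries[[sid]] <- list(scenario_id = sid, status = "failed",
                             error = conditionMessage(res))
      next
    }
    traj_file <- file.path(out_dir, paste0(sid, "_trajectory.csv"))
    summ_file <- file.path(out_dir, paste0(sid, "_summary.csv"))
    traj <- cbind(scenario_id = sid, res$trajectory)
    utils::write.csv(traj, traj_file, row.names = FALSE)
    utils::write.csv(res$summary, summ_file, row.names = FALSE)
    cfg <- config
    cfg$fitness <- list(ro = as.data.frame(cfg$fitness$ro),
                        cost = as.list(cfg$fitness$cost))
    cfg$scheme <- cfg$scheme[c("stay", "migrate")]
    entries[[sid]] <- list(
      scenario_id = sid, status = "ok",
      config = unclass(cfg),
      replicate_seeds = vapply(seq_len(config$replicates), function(i)
        derive_seed(config$seed, i), integer(1)),
      payoff_provenance = as.list(res$payoff_provenance),
      trajectory_file = basename(traj_file),
      summary_file = basename(summ_file))
  }
  manifest <- list(scenarios = entries,
                   package_version = as.character(
                     utils::packageVersion("refugeCA")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat("Scenario:", scenario_id(cfg), "\n")
  cat(" ", cfg$replicates, "replicates x", cfg$generations,
      "generations on a", cfg$height, "x", cfg$width, "lattice\n")
  fin <- x$summary[x$summary$generation == max(x$summary$generation), ]
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  %s final mean p_R = %s (n_alive = %d)\n",
                fin$species[i],
                ifelse(is.na(fin$mean_p_R[i]), "extinct",
                       sprintf("%.4f", fin$mean_p_R[i])),
                fin$n_alive[i]))
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  tab <- table(object$terminal$species, object$terminal$state)
  print(object)
  cat("Terminal states over replicates:\n")
  print(tab)
  invisible(list(summary = object$summary, terminal = tab))
}

#' Plot mean allele-frequency trajectories with replicate envelopes
#'
#' @param x A `scenario_result`.
#' @param species Species to plot (default: all present).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scenario_result <- function(x, species = SPECIES, ...) {
  s <- x$summary[x$summary$species %in% species & !is.na(x$summary$mean_p_R), ]
  if (!nrow(s)) {
    warning("nothing to plot: all replicates extinct")
    return(invisible(x))
  }
  cols <- c(SF = "#1b7837", HA = "#762a83")
  graphics::plot(NA, xlim = range(s$generation), ylim = c(0, 1),
                 xlab = "generation", ylab = "resistance allele frequency",
                 main = scenario_id(x$config), ...)
  for (sp in unique(s$species)) {
    d <- s[s$species == sp, ]
    graphics::polygon(c(d$generation, rev(d$generation)),
                      c(d$env_lo, rev(d$env_hi)),
                      col = grDevices::adjustcolor(cols[[sp]], 0.2),
                      border = NA)
    graphics::lines(d$generation, d$mean_p_R, col = cols[[sp]], lwd = 2)
  }
  graphics::legend("topleft", legend = unique(s$species),
                   col = cols[unique(s$species)], lwd = 2, bty = "n")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", scenario_id(x), "\n")
  cat(sprintf("  %d x %d lattice | %d replicates x %d generations\n",
              x$height, x$width, x$replicates, x$generations))
  cat(sprintf("  p_R = %g, occupancy = %g, species mix (SF) = %g, seed = %d\n",
              x$p_R, x$occupancy, x$species_mix, x$seed))
  invisible(x)
}
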