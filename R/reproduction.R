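## Survivor-to-adult transition, quadrant-structured adult dispersal
## (50% stay, 25% to each of the two orthogonal neighbor quadrants),
## within-quadrant random mating with fecundity-weighted gametes, and
## oviposition into empty cells with probability W given by relative
## fitness pressure in the Moore neighborhood.

QUADRANTS <- c("A", "B", "C", "D")
## 2 x 2 layout: A top-left, B top-right, C bottom-left, D bottom-right;
## neighbors are the orthogonal pairs (no diagonal migration)
QUADRANT_NEIGHBORS <- list(A = c("B", "C"), B = c("A", "D"),
                           C = c("A", "D"), D = c("B", "C"))

#' Default quadrant dispersal scheme
#'
#' Adults remain in their natal quadrant with probability 0.50 and move
#' to each of the two orthogonal neighbor quadrants with probability 0.25.
#'
#' @return List with `stay`, `migrate` (per-neighbor rate) and the
#'   neighbor map.
#' @export
default_quadrant_scheme <- function() {
  list(stay = 0.50, migrate = 0.25, neighbors = QUADRANT_NEIGHBORS)
}

.check_scheme <- function(scheme) {
  if (abs(scheme$stay + 2 * scheme$migrate - 1) > 1e-12)
    stop("quadrant scheme rates must satisfy stay + 2 * migrate = 1",
         call. = FALSE)
  scheme
}

## quadrant id (1..4 = A..D) for each cell, as a matrix parallel to the grid
.quadrant_map <- function(height, width) {
  top <- seq_len(height) <= height %/% 2
  left <- seq_len(width) <= width %/% 2
  q <- outer(top, left, function(t, l) ifelse(t, ifelse(l, 1L, 2L),
                                              ifelse(l, 3L, 4L)))
  q
}

#' Default reproductive-capacity table
#'
#' Relative reproductive capacities (Ro, dimensionless) per species and
#' crop, reflecting the species' host-plant rankings (corn is the primary
#' host of *S. frugiperda*; *H. armigera* does relatively better in cotton
#' and soybean than in corn), and the fractional fecundity costs of
#' resistance: 25% for RR homozygotes, none for heterozygotes (resistance
#' is incompletely recessive and the cost is attributed to resistant
#' individuals).
#'
#' @param cost_RR,cost_RS Fractional fecundity reductions in `[0, 1]`.
#' @return List with `ro` (2 x 3 species-by-crop matrix) and `cost`
#'   (named vector over genotypes).
#' @export
default_fitness_table <- function(cost_RR = 0.25, cost_RS = 0) {
  for (v in c(cost_RR, cost_RS))
    if (v < 0 || v > 1) stop("fitness costs must lie in [0, 1]",
                             call. = FALSE)
  ro <- matrix(c(0.6, 1.0, 0.8,
                 1.0, 0.5, 1.0),
               nrow = 2, byrow = TRUE,
               dimnames = list(SPECIES, CROPS))
  list(ro = ro, cost = c(SS = 0, RS = cost_RS, RR = cost_RR))
}

.check_fitness <- function(fitness, crop) {
  if (!is.list(fitness) || !all(c("ro", "cost") %in% names(fitness)))
    stop("'fitness' must be a list with elements 'ro' and 'cost'",
         call. = FALSE)
  if (!crop %in% colnames(fitness$ro))
    stop("fitness table has no Ro column for crop '", crop, "'",
         call. = FALSE)
  if (any(fitness$ro[, crop] <= 0))
    stop("Ro must be positive for every species", call. = FALSE)
  fitness
}

## effective Ro per genotype for one species on one crop
.effective_ro <- function(fitness, species, crop) {
  fitness$ro[species, crop] * (1 - fitness$cost[GENOTYPES])
}

#' Collect lattice survivors into quadrant adult pools
#'
#' Every surviving larva becomes one adult in the pool of the quadrant
#' containing its cell.
#'
#' @param lattice A `ca_lattice`.
#' @return A 4 x 2 x 3 array of counts (quadrant x species x genotype),
#'   class `adult_pools`; totals equal the lattice's occupied-cell count.
#' @export
survivors_to_pools <- function(lattice) {
  stopifnot(inherits(lattice, "ca_lattice"))
  q <- .quadrant_map(lattice$height, lattice$width)
  pools <- array(0L, dim = c(4, 2, 3),
                 dimnames = list(QUADRANTS, SPECIES, GENOTYPES))
  occ <- lattice$grid > 0L
  if (any(occ)) {
    code <- lattice$grid[occ]
    sp <- (code - 1L) %/% 3L + 1L
    geno <- (code - 1L) %% 3L + 1L
    t3 <- table(factor(q[occ], 1:4), factor(sp, 1:2), factor(geno, 1:3))
    pools[] <- as.integer(t3)
  }
  class(pools) <- c("adult_pools", class(pools))
  pools
}

#' Disperse adults between quadrants
#'
#' Each adult independently stays in its quadrant with probability
#' `scheme$stay` or moves to one of the two orthogonal neighbor quadrants
#' with probability `scheme$migrate` each (multinomial per quadrant,
#' species and genotype); the total adult count is conserved exactly.
#'
#' @param pools An `adult_pools` array from [survivors_to_pools()].
#' @param scheme A quadrant scheme, see [default_quadrant_scheme()].
#' @return The post-dispersal `adult_pools` array.
#' @export
disperse <- function(pools, scheme = default_quadrant_scheme()) {
  .check_scheme(scheme)
  out <- pools
  out[] <- 0L
  for (qi in seq_along(QUADRANTS)) {
    nb <- match(scheme$neighbors[[QUADRANTS[qi]]], QUADRANTS)
    for (si in seq_along(SPECIES)) for (gi in seq_along(GENOTYPES)) {
      n <- pools[qi, si, gi]
      if (n > 0) {
        moves <- stats::rmultinom(1, n, c(scheme$stay, scheme$migrate,
                                          scheme$migrate))
        out[qi, si, gi] <- out[qi, si, gi] + moves[1]
        out[nb[1], si, gi] <- out[nb[1], si, gi] + moves[2]
        out[nb[2], si, gi] <- out[nb[2], si, gi] + moves[3]
      }
    }
  }
  out
}

#' Per-species reproductive success of an adult pool
#'
#' The egg weight of each species is the sum over genotypes of adult count
#' times effective reproductive capacity, where the effective Ro of a
#' genotype is `Ro(species, crop) * (1 - cost(genotype))`.
#'
#' @param pool A 2 x 3 species-by-genotype count matrix (one quadrant's
#'   pool, e.g. `pools["A", , ]`).
#' @param fitness A fitness table, see [default_fitness_table()].
#' @param crop Crop name.
#' @return Named numeric vector `c(SF = , HA = )` of egg weights.
#' @export
reproductive_success <- function(pool, fitness = default_fitness_table(),
                                 crop) {
  crop <- match.arg(crop, CROPS)
  .check_fitness(fitness, crop)
  vapply(SPECIES, function(sp)
    sum(pool[sp, GENOTYPES] * .effective_ro(fitness, sp, crop)),
    numeric(1))
}

## fecundity-weighted offspring genotype distribution for one species'
## quadrant pool: each adult contributes gametes in proportion to its
## effective Ro, so the gamete pool carries R at frequency
## (2 w_RR n_RR + w_RS n_RS) / (2 sum w_g n_g); offspring are
## Hardy-Weinberg at that frequency. NULL if the pool is empty or carries
## zero total weight.
.mating_distribution <- function(counts, eff_ro) {
  w <- counts * eff_ro
  tw <- sum(w)
  if (tw <= 0) return(NULL)
  p_w <- (2 * w[["RR"]] + w[["RS"]]) / (2 * tw)
  hw_genotype_frequencies(p_w)
}

#' Colonization probability of an empty cell
#'
#' An empty cell is colonized with per-species probability `W`: the number
#' of that species' larvae among the 8 Moore neighbors times the mean
#' effective reproductive capacity of the species' quadrant adult pool,
#' normalized by 8 times the maximum effective Ro over species and
#' genotypes on the crop. A cell whose window holds 8 larvae of the
#' maximum-fitness strain reaches `W = 1`; no neighbors or an empty (or
#' zero-weight) quadrant pool gives `W = 0`.
#'
#' @param view A [neighborhood_view()] of an empty cell.
#' @param pool The cell's quadrant pool, a 2 x 3 species-by-genotype
#'   count matrix.
#' @inheritParams reproductive_success
#' @return Named numeric vector `c(SF = , HA = )`; the total
#'   colonization probability is their sum (at most 1).
#' @export
occupation_probability <- function(view, pool,
                                   fitness = default_fitness_table(), crop) {
  crop <- match.arg(crop, CROPS)
  .check_fitness(fitness, crop)
  if (!is.na(view$focal))
    stop("occupation probability is defined for empty cells only",
         call. = FALSE)
  nb <- view$neighbors[!is.na(view$neighbors)]
  nb_sp <- vapply(nb, function(s) .split_strain(s)$species, character(1))
  max_ro <- max(vapply(SPECIES, function(sp)
    max(.effective_ro(fitness, sp, crop)), numeric(1)))
  vapply(SPECIES, function(sp) {
    n_nb <- sum(nb_sp == sp)
    n_pool <- sum(pool[sp, ])
    if (n_nb == 0 || n_pool == 0) return(0)
    mean_ro <- sum(pool[sp, GENOTYPES] * .effective_ro(fitness, sp, crop)) /
      n_pool
    n_nb * mean_ro / (8 * max_ro)
  }, numeric(1))
}

#' Reproduction phase: oviposition into empty cells
#'
#' Every empty cell is tested once for colonization: a single uniform draw
#' against the summed per-species probabilities `W` (see
#' [occupation_probability()]), a fecundity-weighted lottery between the
#' species, and a genotype drawn from the colonizing species'
#' within-quadrant random-mating distribution (fecundity-weighted gamete
#' pool). Occupied cells are unchanged; the generation counter advances
#' by 1.
#'
#' @param lattice The post-competition `ca_lattice`.
#' @param pools Post-dispersal `adult_pools`.
#' @inheritParams reproductive_success
#' @return The next generation's `ca_lattice`.
#' @export
reproduction_phase <- function(lattice, pools,
                               fitness = default_fitness_table(), crop) {
  stopifnot(inherits(lattice, "ca_lattice"))
  crop <- match.arg(crop, CROPS)
  .check_fitness(fitness, crop)
  g <- as.vector(lattice$grid)
  empty <- which(g == 0L)
  lattice$generation <- lattice$generation + 1L
  if (!length(empty) || sum(pools) == 0) {
    return(lattice)
  }

  eff <- rbind(SF = .effective_ro(fitness, "SF", crop),
               HA = .effective_ro(fitness, "HA", crop))
  max_ro <- max(eff)
  ## per-quadrant, per-species mean effective Ro and mating distribution
  mean_ro <- matrix(0, 4, 2, dimnames = list(QUADRANTS, SPECIES))
  mate_cum <- array(NA_real_, dim = c(4, 2, 3))
  for (qi in 1:4) for (si in 1:2) {
    n <- pools[qi, si, ]
    if (sum(n) > 0) {
      mean_ro[qi, si] <- sum(n * eff[si, ]) / sum(n)
      dist <- .mating_distribution(stats::setNames(n, GENOTYPES), eff[si, ])
      if (!is.null(dist)) mate_cum[qi, si, ] <- cumsum(dist)
    }
  }

  cnt <- .neighbor_counts(lattice$grid)
  nb_sf <- rowSums(cnt[empty, 1:3, drop = FALSE])
  nb_ha <- rowSums(cnt[empty, 4:6, drop = FALSE])
  qmap <- as.vector(.quadrant_map(lattice$height, lattice$width))
  q <- qmap[empty]

  w_sf <- nb_sf * mean_ro[cbind(q, 1L)] / (8 * max_ro)
  w_ha <- nb_ha * mean_ro[cbind(q, 2L)] / (8 * max_ro)
  ## a species with a zero-weight gamete pool cannot produce offspring
  w_sf[is.na(mate_cum[cbind(q, 1L, 3L)])] <- 0
  w_ha[is.na(mate_cum[cbind(q, 2L, 3L)])] <- 0
  w_tot <- w_sf + w_ha

  u1 <- stats::runif(length(empty))
  col_idx <- which(u1 < w_tot)
  if (length(col_idx)) {
    u2 <- stats::runif(length(col_idx))
    is_sf <- u2 * w_tot[col_idx] < w_sf[col_idx]
    si <- ifelse(is_sf, 1L, 2L)
    qc <- q[col_idx]
    u3 <- stats::runif(length(col_idx))
    geno <- 1L +
      (u3 > mate_cum[cbind(qc, si, 1L)]) +
      (u3 > mate_cum[cbind(qc, si, 2L)])
    g[empty[col_idx]] <- (si - 1L) * 3L + geno
  }
  lattice$grid <- matrix(g, nrow = lattice$height, ncol = lattice$width)
  lattice
}
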