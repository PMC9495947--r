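## Cellular-automaton lattice: toroidal grid, one larva per cell at most,
## Moore neighborhood of radius 1 (the 3 x 3 window around a focal cell).
## Cells hold integer strain codes (0 = empty, 1..6 = strain; see
## STRAIN_CODES). The competition phase is a synchronous (parallel) update:
## every cell is resolved against the pre-update state.

MOORE_OFFSETS <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))
MOORE_OFFSETS <- MOORE_OFFSETS[!(MOORE_OFFSETS[, 1] == 0 &
                                   MOORE_OFFSETS[, 2] == 0), ]

#' Initialize a lattice
#'
#' Each cell is independently occupied with probability `occupancy`;
#' occupied cells are assigned a species by the species mix and a genotype
#' drawn from the Hardy-Weinberg distribution at that species' initial
#' resistance-allele frequency.
#'
#' @param width,height Grid dimensions in cells (default 100 x 100).
#' @param occupancy Probability a cell starts occupied, in `[0, 1]`.
#' @param species_mix Probability an occupied cell is *S. frugiperda*
#'   (`1` gives a single-species SF lattice, `0` a single-species HA one).
#' @param p_R Initial resistance-allele frequency, a single value for both
#'   species or a named vector `c(SF = , HA = )`.
#' @return A `ca_lattice` object (fields `grid`, `width`, `height`,
#'   `generation`).
#' @examples
#' set.seed(1)
#' lat <- init_lattice(width = 20, height = 20, p_R = 0.1)
#' lattice_counts(lat)
#' @export
init_lattice <- function(width = 100, height = 100, occupancy = 0.5,
                         species_mix = 0.5, p_R = 0.1) {
  for (nm in c("occupancy", "species_mix")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a single number in [0, 1]", call. = FALSE)
  }
  if (length(p_R) == 1L && is.null(names(p_R))) p_R <- c(SF = p_R, HA = p_R)
  if (!all(SPECIES %in% names(p_R)))
    stop("'p_R' must be a single value or named c(SF = , HA = )",
         call. = FALSE)
  for (sp in SPECIES)
    if (p_R[[sp]] < 0 || p_R[[sp]] > 1)
      stop("'p_R' must lie in [0, 1]", call. = FALSE)
  if (width < 3 || height < 3)
    stop("lattice must be at least 3 x 3 for a radius-1 Moore neighborhood",
         call. = FALSE)

  ncell <- width * height
  g <- integer(ncell)
  occ <- stats::runif(ncell) < occupancy
  n_occ <- sum(occ)
  if (n_occ) {
    is_sf <- stats::runif(n_occ) < species_mix
    geno <- integer(n_occ)
    for (sp in SPECIES) {
      sel <- if (sp == "SF") is_sf else !is_sf
      n_sp <- sum(sel)
      if (n_sp)
        geno[sel] <- sample.int(3L, n_sp, replace = TRUE,
                                prob = hw_genotype_frequencies(p_R[[sp]]))
    }
    g[occ] <- ifelse(is_sf, 0L, 3L) + geno
  }
  structure(list(grid = matrix(g, nrow = height, ncol = width),
                 width = as.integer(width), height = as.integer(height),
                 generation = 0L),
            class = "ca_lattice")
}

## shifted copy of the grid: S[i, j] = grid[wrap(i + dr), wrap(j + dc)]
.torus_shift <- function(grid, dr, dc) {
  h <- nrow(grid); w <- ncol(grid)
  ri <- ((seq_len(h) - 1L + dr) %% h) + 1L
  ci <- ((seq_len(w) - 1L + dc) %% w) + 1L
  grid[ri, ci, drop = FALSE]
}

## ncell x 6 matrix of Moore-neighbor counts per strain code
.neighbor_counts <- function(grid) {
  ncell <- length(grid)
  cnt <- matrix(0L, ncell, 6L)
  for (i in seq_len(nrow(MOORE_OFFSETS))) {
    s <- as.vector(.torus_shift(grid, MOORE_OFFSETS[i, 1], MOORE_OFFSETS[i, 2]))
    occ <- s > 0L
    if (any(occ)) {
      idx <- cbind(which(occ), s[occ])
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  cnt
}

#' Extract the 3 x 3 neighborhood view of a cell
#'
#' @param lattice A `ca_lattice`.
#' @param row,col 1-based cell coordinates.
#' @return List with `focal` (strain key or `NA` if empty) and
#'   `neighbors` (character vector of the 8 Moore neighbors, `NA` for
#'   empty cells; toroidal wrap-around).
#' @export
neighborhood_view <- function(lattice, row, col) {
  stopifnot(inherits(lattice, "ca_lattice"))
  g <- lattice$grid
  h <- nrow(g); w <- ncol(g)
  if (row < 1 || row > h || col < 1 || col > w)
    stop("cell coordinates out of range", call. = FALSE)
  codes <- vapply(seq_len(nrow(MOORE_OFFSETS)), function(i) {
    g[((row - 1L + MOORE_OFFSETS[i, 1]) %% h) + 1L,
      ((col - 1L + MOORE_OFFSETS[i, 2]) %% w) + 1L]
  }, integer(1))
  to_key <- function(code) if (code > 0L) names(STRAIN_CODES)[code] else
    NA_character_
  list(focal = to_key(g[row, col]),
       neighbors = vapply(codes, to_key, character(1)))
}

.eligible_neighbors <- function(view, mode) {
  nb <- view$neighbors[!is.na(view$neighbors)]
  if (mode == "intra_only") {
    focal_sp <- .split_strain(view$focal)$species
    nb <- nb[vapply(nb, function(s) .split_strain(s)$species,
                    character(1)) == focal_sp]
  }
  nb
}

#' Encounter probability of a focal larva
#'
#' The probability that a focal larva meets a competitor this generation
#' is the occupancy rate of eligible competitors in its 3 x 3 window: the
#' number of eligible larvae among the 8 Moore neighbors, divided by 8.
#' The focal larva is never its own competitor. Eligibility is same
#' species in `intra_only` mode, any larva in `intra_plus_inter`.
#'
#' @param view A [neighborhood_view()] with an occupied focal cell.
#' @param mode `"intra_only"` or `"intra_plus_inter"`.
#' @return Probability in `[0, 1]`.
#' @export
encounter_probability <- function(view,
                                  mode = c("intra_plus_inter", "intra_only")) {
  mode <- match.arg(mode)
  if (is.na(view$focal))
    stop("focal cell is empty: encounter probability undefined",
         call. = FALSE)
  length(.eligible_neighbors(view, mode)) / 8
}

#' Draw an encounter for a focal larva
#'
#' A uniform draw on (0.00001, 1) is compared to the encounter
#' probability; on an encounter, the opponent is sampled uniformly among
#' the eligible larvae in the window.
#'
#' @inheritParams encounter_probability
#' @return The opponent's strain key, or `NULL` if no encounter occurs.
#' @export
draw_encounter <- function(view, mode = c("intra_plus_inter", "intra_only")) {
  mode <- match.arg(mode)
  p <- encounter_probability(view, mode)
  u <- stats::runif(1, min = 0.00001, max = 1)
  if (u > p) return(NULL)
  nb <- .eligible_neighbors(view, mode)
  nb[[sample.int(length(nb), 1L)]]
}

#' Resolve survival of one competition encounter
#'
#' @param focal,opponent Strain keys.
#' @param payoffs An expanded `payoff_matrix`.
#' @return `TRUE` (alive) with probability `rho_s = ` focal's survival
#'   payoff against the opponent, else `FALSE` (dead).
#' @export
resolve_survival <- function(focal, opponent, payoffs) {
  rho <- payoff_lookup(payoffs, focal, opponent)
  stats::runif(1) < rho
}

#' Synchronous competition phase
#'
#' Every occupied cell is evaluated against the pre-update lattice state:
#' a single uniform draw on (0.00001, 1) per cell decides whether the
#' larva meets a competitor (probability = eligible window occupancy / 8);
#' on an encounter one opponent is drawn uniformly among eligible
#' neighbors and the focal larva survives with probability `rho_s` from
#' the payoff matrix. Dead larvae leave their cells empty; larvae with no
#' encounter are unaffected. At most one encounter per larva per
#' generation.
#'
#' @param lattice A `ca_lattice`.
#' @param payoffs An expanded `payoff_matrix`; its `mode` selects
#'   eligibility (same species only, or any larva).
#' @return The post-competition `ca_lattice` (same generation counter).
#' @export
competition_phase <- function(lattice, payoffs) {
  stopifnot(inherits(lattice, "ca_lattice"))
  rho <- payoff_array(payoffs)
  mode <- payoffs$mode
  g <- as.vector(lattice$grid)
  occ <- which(g > 0L)
  if (!length(occ)) return(lattice)

  cnt <- .neighbor_counts(lattice$grid)
  elig <- cnt[occ, , drop = FALSE]
  if (mode == "intra_only") {
    focal_sf <- g[occ] <= 3L
    elig[focal_sf, 4:6] <- 0L
    elig[!focal_sf, 1:3] <- 0L
  }
  n_elig <- rowSums(elig)
  p_enc <- n_elig / 8

  u <- stats::runif(length(occ), min = 0.00001, max = 1)
  enc <- u <= p_enc & n_elig > 0L
  if (any(enc)) {
    E <- elig[enc, , drop = FALSE]
    tot <- rowSums(E)
    r <- stats::runif(nrow(E)) * tot
    cs <- E %*% upper.tri(diag(6), diag = TRUE)  # row-wise cumulative sums
    opp <- 1L + rowSums(cs < r)
    focal <- g[occ][enc]
    ps <- rho[cbind(focal, opp)]
    if (anyNA(ps))
      stop("missing payoff entry for an encountered strain pair",
           call. = FALSE)
    dead <- stats::runif(length(ps)) >= ps
    g[occ[enc][dead]] <- 0L
  }
  lattice$grid <- matrix(g, nrow = lattice$height, ncol = lattice$width)
  lattice
}

#' Genotype counts per species on the lattice
#'
#' @param lattice A `ca_lattice`.
#' @return List with elements `SF` and `HA`, each a named count vector
#'   `c(SS, RS, RR)`.
#' @export
lattice_counts <- function(lattice) {
  stopifnot(inherits(lattice, "ca_lattice"))
  tab <- tabulate(lattice$grid, nbins = 6L)
  list(SF = c(SS = tab[1], RS = tab[2], RR = tab[3]),
       HA = c(SS = tab[4], RS = tab[5], RR = tab[6]))
}

#' @export
print.ca_lattice <- function(x, ...) {
  n_occ <- sum(x$grid > 0L)
  cat("ca_lattice", x$height, "x", x$width, "| generation", x$generation,
      "|", n_occ, "occupied cells\n")
  cnt <- lattice_counts(x)
  for (sp in SPECIES)
    cat(" ", sp, ":", paste(names(cnt[[sp]]), cnt[[sp]], sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Lattice snapshot as a data frame
#'
#' One row per occupied cell: generation, row, col, species, genotype.
#'
#' @param x A `ca_lattice`.
#' @param ... Unused.
#' @export
as.data.frame.ca_lattice <- function(x, ...) {
  idx <- which(x$grid > 0L, arr.ind = TRUE)
  code <- x$grid[idx]
  data.frame(generation = x$generation,
             row = idx[, 1], col = idx[, 2],
             species = CODE_SPECIES[code],
             genotype = CODE_GENOTYPE[code],
             stringsAsFactors = FALSE)
}
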