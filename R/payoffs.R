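## Strain-vs-strain survival payoff matrices per crop and interaction mode.
##
## A payoff matrix entry (focal, opponent) -> rho_s is the probability that
## a FOCAL larva survives a five-day competition encounter with an OPPONENT
## larva. Matrices are ordered, never symmetric: the two sides of the same
## pairing come from the two species'/strains' own survival, which the
## bioassays measured separately. Intraspecific and interspecific entries
## come from two separate experiments and are kept as separate strata.

CROPS <- c("cotton", "corn", "soybean")
INTERACTION_MODES <- c("intra_only", "intra_plus_inter")
HETEROZYGOTE_BEHAVIORS <- c("BH_00RR", "BH_50RR", "BH_100RR")

#' Construct a strain key
#'
#' A strain is a (species, genotype) competitor class: `"SF"` or `"HA"`
#' crossed with `"SS"`, `"RS"`, `"RR"`.
#'
#' @param species `"SF"` (*Spodoptera frugiperda*) or `"HA"`
#'   (*Helicoverpa armigera*).
#' @param genotype `"SS"`, `"RS"` or `"RR"`.
#' @return Length-1 character, e.g. `"SF-RR"`.
#' @export
strain_key <- function(species, genotype) {
  species <- match.arg(species, SPECIES)
  genotype <- match.arg(genotype, GENOTYPES)
  paste(species, genotype, sep = "-")
}

## integer strain codes used by the lattice engine:
## 1 SF-SS, 2 SF-RS, 3 SF-RR, 4 HA-SS, 5 HA-RS, 6 HA-RR
STRAIN_CODES <- c("SF-SS" = 1L, "SF-RS" = 2L, "SF-RR" = 3L,
                  "HA-SS" = 4L, "HA-RS" = 5L, "HA-RR" = 6L)
CODE_SPECIES <- c("SF", "SF", "SF", "HA", "HA", "HA")
CODE_GENOTYPE <- c("SS", "RS", "RR", "SS", "RS", "RR")

.new_payoff_matrix <- function(entries, crop, mode, expanded = NA_character_) {
  rownames(entries) <- NULL
  structure(list(entries = entries, crop = crop, mode = mode,
                 expanded = expanded),
            class = "payoff_matrix")
}

.entry_key <- function(df) {
  paste(df$interaction, df$focal_species, df$focal_genotype,
        df$opponent_species, df$opponent_genotype, sep = "|")
}

## all ordered homozygote pairs a complete fixture must contain
.homozygote_grid <- function() {
  hz <- c("SS", "RR")
  intra <- do.call(rbind, lapply(SPECIES, function(sp)
    expand.grid(interaction = "intra",
                focal_species = sp, focal_genotype = hz,
                opponent_species = sp, opponent_genotype = hz,
                stringsAsFactors = FALSE)))
  inter <- do.call(rbind, lapply(SPECIES, function(sp)
    expand.grid(interaction = "inter",
                focal_species = sp, focal_genotype = hz,
                opponent_species = setdiff(SPECIES, sp),
                opponent_genotype = hz,
                stringsAsFactors = FALSE)))
  rbind(intra, inter)
}

#' Load a per-crop payoff fixture
#'
#' Reads the shipped fixture of printed five-day survival probabilities for
#' one crop (or a user fixture in the same CSV schema) and fills any
#' homozygote cell the bioassay write-up did not print with the default
#' policy: the mean of the focal species' printed values for the same crop
#' and interaction stratum (intra or inter), flagged `"default"` so
#' downstream outputs can report how much of a run rests on gap-filled
#' cells.
#'
#' @param crop `"cotton"`, `"corn"` or `"soybean"`.
#' @param path Optional path to a fixture CSV; defaults to the fixture
#'   shipped with the package.
#' @param mode Interaction mode the matrix will be used in,
#'   `"intra_plus_inter"` (default) or `"intra_only"`. In `"intra_only"`
#'   mode interspecific entries are inert: [payoff_lookup()] refuses them.
#' @return A `payoff_matrix` object holding homozygote (SS/RR) entries
#'   only; expand with [expand_heterozygotes()] before simulating.
#' @seealso [expand_heterozygotes()], [payoff_lookup()],
#'   [write_payoff_fixture()]
#' @export
load_payoff_fixture <- function(crop, path = NULL,
                                mode = c("intra_plus_inter", "intra_only")) {
  crop <- match.arg(crop, CROPS)
  mode <- match.arg(mode)
  if (is.null(path))
    path <- system.file("extdata", paste0("payoffs_", crop, ".csv"),
                        package = "refugeCA", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rho_s = "character"))
  required <- c("crop", "interaction", "focal_species", "focal_genotype",
                "opponent_species", "opponent_genotype", "rho_s", "provenance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("fixture is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"note" %in% names(df)) df$note <- ""
  ## rho_s read as character so a written fixture round-trips bit-exactly;
  ## numeric value validated here
  df$rho_num <- as.numeric(df$rho_s)
  if (any(is.na(df$rho_num)) || any(df$rho_num < 0) || any(df$rho_num > 1))
    stop("fixture contains rho_s outside [0, 1]", call. = FALSE)
  if (any(df$crop != crop))
    stop("fixture crop column does not match '", crop, "'", call. = FALSE)

  grid <- .homozygote_grid()
  have <- .entry_key(df)
  need <- .entry_key(grid)
  fill <- grid[!(need %in% have), , drop = FALSE]
  if (nrow(fill)) {
    fill$crop <- crop
    fill$rho_num <- vapply(seq_len(nrow(fill)), function(i) {
      src <- df$provenance == "printed" &
        df$interaction == fill$interaction[i] &
        df$focal_species == fill$focal_species[i]
      if (!any(src))
        stop("no printed value to derive a default for ",
             fill$focal_species[i], " (", fill$interaction[i], ", ", crop,
             ")", call. = FALSE)
      mean(df$rho_num[src])
    }, numeric(1))
    fill$rho_s <- format(fill$rho_num, digits = 15, trim = TRUE)
    fill$provenance <- "default"
    fill$note <- paste0("unprinted cell; mean of focal species' printed ",
                        fill$interaction, " values for ", crop)
    df <- rbind(df[required_cols <- c(required, "note", "rho_num")],
                fill[required_cols])
  }
  df <- df[order(match(df$interaction, c("intra", "inter")),
                 match(df$focal_species, SPECIES),
                 match(df$focal_genotype, GENOTYPES),
                 match(df$opponent_species, SPECIES),
                 match(df$opponent_genotype, GENOTYPES)), ]
  .new_payoff_matrix(df, crop, mode)
}

#' Write a payoff matrix back to the fixture CSV schema
#'
#' Values are written as their stored character form, so a write/reload
#' round-trip reproduces identical values and provenance flags.
#'
#' @param matrix A `payoff_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_payoff_fixture <- function(matrix, path) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  out <- matrix$entries
  out <- out[c("crop", "interaction", "focal_species", "focal_genotype",
               "opponent_species", "opponent_genotype", "rho_s",
               "provenance", "note")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## genotype image(s) of a strain under a heterozygote-behavior scenario
.bh_images <- function(bh) {
  switch(bh,
         BH_00RR = list(c(RS = "SS")),
         BH_100RR = list(c(RS = "RR")),
         BH_50RR = list(c(RS = "SS"), c(RS = "RR")))
}

#' Expand a homozygote payoff matrix to heterozygotes
#'
#' The bioassays quantified only homozygote (SS, RR) strains; heterozygote
#' competition behavior is a scenario choice. Under `BH_00RR` every entry
#' involving an RS strain copies the entry with that species' SS strain
#' substituted; under `BH_100RR` the RR strain is substituted; under
#' `BH_50RR` each RS-involving entry is the midpoint of the two
#' substituted values (for RS vs RS the substitution is applied to both
#' slots in tandem, so the value is the midpoint of the SS-vs-SS and
#' RR-vs-RR entries). Printed entries are never modified and expansion is
#' idempotent.
#'
#' @param matrix A homozygote-complete `payoff_matrix` from
#'   [load_payoff_fixture()].
#' @param bh `"BH_00RR"`, `"BH_50RR"` or `"BH_100RR"`.
#' @return A `payoff_matrix` with all 6 x 6 strain entries per stratum;
#'   added entries are flagged `"expanded"`.
#' @export
expand_heterozygotes <- function(matrix, bh) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  bh <- match.arg(bh, HETEROZYGOTE_BEHAVIORS)
  if (!is.na(matrix$expanded) && matrix$expanded != bh)
    stop("matrix already expanded under ", matrix$expanded,
         "; re-expand from the homozygote fixture", call. = FALSE)
  df <- matrix$entries
  hom <- df[df$focal_genotype != "RS" & df$opponent_genotype != "RS", ]
  key <- .entry_key(hom)
  grid_all <- .full_grid()
  todo <- grid_all[grid_all$focal_genotype == "RS" |
                     grid_all$opponent_genotype == "RS", , drop = FALSE]
  todo <- todo[!(.entry_key(todo) %in% .entry_key(df)), , drop = FALSE]
  if (nrow(todo)) {
    images <- .bh_images(bh)
    val <- vapply(seq_len(nrow(todo)), function(i) {
      vals <- vapply(images, function(map) {
        fg <- todo$focal_genotype[i]
        og <- todo$opponent_genotype[i]
        if (fg == "RS") fg <- unname(map["RS"])
        if (og == "RS") og <- unname(map["RS"])
        k <- paste(todo$interaction[i], todo$focal_species[i], fg,
                   todo$opponent_species[i], og, sep = "|")
        j <- match(k, key)
        if (is.na(j))
          stop("missing homozygote entry for cell ", k, call. = FALSE)
        hom$rho_num[j]
      }, numeric(1))
      mean(vals)
    }, numeric(1))
    add <- todo
    add$crop <- matrix$crop
    add$rho_num <- val
    add$rho_s <- format(val, digits = 15, trim = TRUE)
    add$provenance <- "expanded"
    add$note <- paste0("heterozygote entry under ", bh)
    df <- rbind(df, add[names(df)])
  }
  df <- df[order(match(df$interaction, c("intra", "inter")),
                 match(df$focal_species, SPECIES),
                 match(df$focal_genotype, GENOTYPES),
                 match(df$opponent_species, SPECIES),
                 match(df$opponent_genotype, GENOTYPES)), ]
  .new_payoff_matrix(df, matrix$crop, matrix$mode, expanded = bh)
}

.full_grid <- function() {
  intra <- do.call(rbind, lapply(SPECIES, function(sp)
    expand.grid(interaction = "intra",
                focal_species = sp, focal_genotype = GENOTYPES,
                opponent_species = sp, opponent_genotype = GENOTYPES,
                stringsAsFactors = FALSE)))
  inter <- do.call(rbind, lapply(SPECIES, function(sp)
    expand.grid(interaction = "inter",
                focal_species = sp, focal_genotype = GENOTYPES,
                opponent_species = setdiff(SPECIES, sp),
                opponent_genotype = GENOTYPES,
                stringsAsFactors = FALSE)))
  rbind(intra, inter)
}

#' Look up a focal strain's survival probability against an opponent
#'
#' Same-species pairs use the intraspecific stratum, cross-species pairs
#' the interspecific stratum. In `intra_only` mode cross-species lookups
#' are refused.
#'
#' @param matrix A `payoff_matrix`.
#' @param focal,opponent Strain keys such as `"SF-SS"` (see
#'   [strain_key()]).
#' @return The survival probability rho_s in `[0, 1]`.
#' @export
payoff_lookup <- function(matrix, focal, opponent) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  f <- .split_strain(focal)
  o <- .split_strain(opponent)
  interaction <- if (f$species == o$species) "intra" else "inter"
  if (interaction == "inter" && matrix$mode == "intra_only")
    stop("interspecific lookup in intra_only mode: ", focal, " vs ", opponent,
         call. = FALSE)
  df <- matrix$entries
  j <- which(df$interaction == interaction &
               df$focal_species == f$species &
               df$focal_genotype == f$genotype &
               df$opponent_species == o$species &
               df$opponent_genotype == o$genotype)
  if (!length(j))
    stop("no payoff entry for ", focal, " vs ", opponent,
         " (expand heterozygotes first?)", call. = FALSE)
  df$rho_num[j[1]]
}

.split_strain <- function(strain) {
  if (!is.character(strain) || length(strain) != 1L ||
      !strain %in% names(STRAIN_CODES))
    stop("strain must be one of ", paste(names(STRAIN_CODES), collapse = ", "),
         call. = FALSE)
  code <- STRAIN_CODES[[strain]]
  list(species = CODE_SPECIES[code], genotype = CODE_GENOTYPE[code],
       code = code)
}

## 6 x 6 numeric matrix rho[focal code, opponent code] for the engine;
## cross-species cells are NA in intra_only mode
payoff_array <- function(matrix) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  if (is.na(matrix$expanded))
    stop("payoff matrix must be heterozygote-expanded before simulation",
         call. = FALSE)
  rho <- matrix(NA_real_, 6, 6,
                dimnames = list(names(STRAIN_CODES), names(STRAIN_CODES)))
  df <- matrix$entries
  for (i in seq_len(nrow(df))) {
    fc <- STRAIN_CODES[[paste(df$focal_species[i], df$focal_genotype[i],
                              sep = "-")]]
    oc <- STRAIN_CODES[[paste(df$opponent_species[i], df$opponent_genotype[i],
                              sep = "-")]]
    rho[fc, oc] <- df$rho_num[i]
  }
  if (matrix$mode == "intra_only") {
    rho[1:3, 4:6] <- NA_real_
    rho[4:6, 1:3] <- NA_real_
  }
  rho
}

#' @export
print.payoff_matrix <- function(x, ...) {
  prov <- table(x$entries$provenance)
  cat("Payoff matrix (five-day survival rho_s), crop:", x$crop,
      "| mode:", x$mode, "\n")
  cat("Heterozygote expansion:",
      if (is.na(x$expanded)) "none (homozygotes only)" else x$expanded, "\n")
  cat("Entries:", nrow(x$entries), "(",
      paste(names(prov), as.integer(prov), sep = ": ", collapse = ", "),
      ")\n")
  invisible(x)
}
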