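## Survival-analysis layer for the competition bioassays: a synthetic
## record generator calibrated to a five-day survival endpoint,
## Kaplan-Meier product-limit estimation, two-sample log-rank comparison,
## and payoff extraction at day 5. Estimation is delegated to the survival
## package (survfit/survdiff) behind this module's interface.

#' Simulate a competition bioassay arm
#'
#' Generates per-larva time-to-death records under a constant daily
#' hazard `h` calibrated so that five-day survival equals `true_rho`
#' (`(1 - h)^days = true_rho`); larvae alive after the last day are
#' censored there. The cage (block) structure of the assay design is
#' carried in the records but ignored by the estimators.
#'
#' @param true_rho True end-of-assay survival probability in `[0, 1]`.
#' @param cages Number of replicate cages (default 4).
#' @param larvae_per_cage Larvae of the arm per cage (default 5).
#' @param days Assay duration in days (default 5).
#' @param arm Arm label stored in the records.
#' @return Data frame of survival records: `subject`, `arm`, `cage`,
#'   `day`, `event` (1 = died, 0 = censored).
#' @examples
#' set.seed(1)
#' rec <- simulate_bioassay(0.6)
#' table(rec$event)
#' @export
simulate_bioassay <- function(true_rho, cages = 4, larvae_per_cage = 5,
                              days = 5, arm = "arm") {
  if (!is.numeric(true_rho) || length(true_rho) != 1L || is.na(true_rho) ||
      true_rho < 0 || true_rho > 1)
    stop("'true_rho' must be a single number in [0, 1]", call. = FALSE)
  if (cages < 1 || larvae_per_cage < 1 || days < 1)
    stop("'cages', 'larvae_per_cage' and 'days' must be positive",
         call. = FALSE)
  n <- cages * larvae_per_cage
  h <- 1 - true_rho^(1 / days)
  if (h >= 1) {
    day <- rep(1L, n)
    event <- rep(1L, n)
  } else if (h <= 0) {
    day <- rep(as.integer(days), n)
    event <- rep(0L, n)
  } else {
    ## geometric death day with support 1, 2, ...; censor past `days`
    d <- stats::rgeom(n, prob = h) + 1L
    event <- as.integer(d <= days)
    day <- as.integer(pmin(d, days))
  }
  data.frame(subject = seq_len(n), arm = arm,
             cage = rep(seq_len(cages), each = larvae_per_cage),
             day = day, event = event, stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  req <- c("day", "event")
  if (!is.data.frame(records) || !all(req %in% names(records)) ||
      nrow(records) == 0)
    stop("'records' must be a non-empty data frame with columns day, event",
         call. = FALSE)
  if (any(records$day < 1))
    stop("'day' must be >= 1", call. = FALSE)
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times <= t of (1 - d_i / n_i)`; censoring
#' reduces risk sets without contributing events.
#'
#' @param records Survival records (see [simulate_bioassay()]).
#' @return A `km_curve`: data frame with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, restricted to the observed time points.
#' @export
km_estimate <- function(records) {
  records <- .check_records(records)
  fit <- survival::survfit(survival::Surv(records$day, records$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Survival probability at a given time from a KM curve
#'
#' @param curve A `km_curve`.
#' @param time Time point (default: last observed time).
#' @return `S(time)`: the product-limit estimate at the latest event time
#'   not exceeding `time` (1 if no event has occurred by then).
#' @export
km_survival_at <- function(curve, time = max(curve$time)) {
  events <- curve[curve$n_event > 0 & curve$time <= time, ]
  if (!nrow(events)) return(1)
  events$surv[nrow(events)]
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom comparing two
#' arms' survival curves. With no events in either arm the statistic is 0
#' and p = 1.
#'
#' @param arm_a,arm_b Survival records of the two arms.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`, class
#'   `log_rank_result`.
#' @export
log_rank <- function(arm_a, arm_b) {
  arm_a <- .check_records(arm_a)
  arm_b <- .check_records(arm_b)
  day <- c(arm_a$day, arm_b$day)
  event <- c(arm_a$event, arm_b$event)
  group <- rep(c("a", "b"), c(nrow(arm_a), nrow(arm_b)))
  if (sum(event) == 0) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    sd <- survival::survdiff(survival::Surv(day, event) ~ group)
    res <- list(statistic = unname(sd$chisq),
                p_value = stats::pchisq(sd$chisq, df = 1,
                                        lower.tail = FALSE))
  }
  structure(res, class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Estimate a payoff-matrix entry from bioassay records
#'
#' The per-encounter survival payoff is the Kaplan-Meier survival
#' estimate at the end of the assay (day 5 by default); without censoring
#' before the end it equals the raw surviving fraction.
#'
#' @param records Survival records of one arm.
#' @param at Assay endpoint day.
#' @return Survival probability in `[0, 1]`.
#' @export
estimate_payoff <- function(records, at = 5) {
  km_survival_at(km_estimate(records), time = at)
}

#' Insert an estimated payoff into a payoff matrix
#'
#' Sets the (focal, opponent) entry of the given stratum to an estimate
#' from bioassay records, flagged `"estimated"`.
#'
#' @param matrix A `payoff_matrix`.
#' @param focal,opponent Strain keys.
#' @param records Survival records for the focal strain's arm.
#' @param at Assay endpoint day.
#' @return The updated `payoff_matrix`.
#' @export
set_estimated_payoff <- function(matrix, focal, opponent, records, at = 5) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  rho <- estimate_payoff(records, at = at)
  f <- .split_strain(focal)
  o <- .split_strain(opponent)
  interaction <- if (f$species == o$species) "intra" else "inter"
  df <- matrix$entries
  j <- which(df$interaction == interaction &
               df$focal_species == f$species &
               df$focal_genotype == f$genotype &
               df$opponent_species == o$species &
               df$opponent_genotype == o$genotype)
  row <- data.frame(crop = matrix$crop, interaction = interaction,
                    focal_species = f$species, focal_genotype = f$genotype,
                    opponent_species = o$species,
                    opponent_genotype = o$genotype,
                    rho_s = format(rho, digits = 15, trim = TRUE),
                    provenance = "estimated",
                    note = "estimated from bioassay records",
                    rho_num = rho, stringsAsFactors = FALSE)
  if (length(j)) df[j[1], ] <- row[names(df)] else df <- rbind(df, row[names(df)])
  .new_payoff_matrix(df, matrix$crop, matrix$mode, matrix$expanded)
}
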