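#' The default experimental design for trial-average tables
#'
#' Six individuals; individuals 1-3 swim in all four viscosities (1, 5, 10,
#' 40 cP), individuals 4-6 only in 1 and 40 cP; two trials per individual
#' per condition, plus a third 1 cP trial for individuals 1 and 2 (38 trials
#' in total). With a random intercept per individual this design yields the
#' conservative denominator df 29 for a 4-level within-individual factor
#' (38 - 6 - 3) and, crossed with three body positions, denominator df 10
#' for position (18 - 6 - 2).
#'
#' @param n_fish number of individuals (default 6).
#' @param viscosities viscosity levels, cP.
#' @return data.frame with one row per trial: `individual`, `viscosity_cp`,
#'   `trial`.
#' @export
paper_design <- function(n_fish = 6, viscosities = c(1, 5, 10, 40)) {
  rows <- list()
  for (f in seq_len(n_fish)) {
    vs <- if (f <= ceiling(n_fish / 2)) viscosities else
      viscosities[c(1, length(viscosities))]
    for (v in vs) {
      k <- 2L + (v == viscosities[1] && f <= 2)  # third 1 cP trial, fish 1-2
      rows[[length(rows) + 1L]] <- data.frame(
        individual = f, viscosity_cp = v, trial = seq_len(k))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a tidy trial-average table with known ground truth
#'
#' Emulates the observation layer of the statistical stage: per-trial mean
#' values of one variable by viscosity (and optionally body position), with
#' individual, individual-by-position and residual variance components. The
#' generating model is
#' \deqn{y = \mu(v, p) + b_{ind} + b_{ind:p} + \varepsilon_p,}
#' with independent Gaussian components; the residual SD may differ by
#' position (the heteroscedasticity the variance-function correction
#' addresses).
#'
#' @param effects data.frame of generating cell means: columns
#'   `viscosity_cp`, `mean`, and optionally `body_position`.
#' @param design trial layout (default [paper_design()] restricted to the
#'   viscosities present in `effects`).
#' @param sd_individual SD of the per-individual random intercept.
#' @param sd_ind_position SD of the individual-by-position intercept.
#' @param sd_resid residual SD; scalar, or named vector by position.
#' @param variable variable name for the output column.
#' @param seed RNG seed.
#' @return A `trial_summary` data.frame: `individual`, `trial`,
#'   `viscosity_cp`, `body_position` (`NA` when positions are absent),
#'   `variable`, `value`, with the generating parameters in
#'   `attr(,"truth")`.
#' @export
simulate_trial_summary <- function(effects, design = NULL,
                                   sd_individual = 0.1,
                                   sd_ind_position = 0,
                                   sd_resid = 0.1,
                                   variable = "y", seed = 1L) {
  stopifnot(is.data.frame(effects),
            all(c("viscosity_cp", "mean") %in% names(effects)))
  if (any(c(sd_individual, sd_ind_position, unlist(sd_resid)) < 0)) {
    stop("variance components must be non-negative")
  }
  has_pos <- "body_position" %in% names(effects) &&
    !all(is.na(effects$body_position))
  design <- design %||% paper_design(viscosities = unique(effects$viscosity_cp))
  positions <- if (has_pos) unique(effects$body_position) else NA
  rows <- merge(design, data.frame(body_position = positions))
  key <- if (has_pos) paste(rows$viscosity_cp, rows$body_position) else
    as.character(rows$viscosity_cp)
  ekey <- if (has_pos) paste(effects$viscosity_cp, effects$body_position) else
    as.character(effects$viscosity_cp)
  mu <- effects$mean[match(key, ekey)]
  if (anyNA(mu)) stop("effects table is missing some viscosity x position cells")
  resid_sd <- if (length(sd_resid) == 1) rep_len(unlist(sd_resid), nrow(rows)) else {
    unlist(sd_resid)[as.character(rows$body_position)]
  }
  if (anyNA(resid_sd)) stop("sd_resid must cover every position")
  with_seed(seed, {
    ind_levels <- unique(rows$individual)
    b_ind <- setNames(rnorm(length(ind_levels), 0, sd_individual),
                      ind_levels)
    ip <- unique(paste(rows$individual, rows$body_position))
    b_ip <- setNames(rnorm(length(ip), 0, sd_ind_position), ip)
    value <- mu + b_ind[as.character(rows$individual)] +
      b_ip[paste(rows$individual, rows$body_position)] +
      rnorm(nrow(rows), 0, resid_sd)
  })
  out <- data.frame(individual = rows$individual, trial = rows$trial,
                    viscosity_cp = rows$viscosity_cp,
                    body_position = if (has_pos) rows$body_position else NA,
                    variable = variable, value = as.numeric(value))
  out <- out[order(out$individual, out$viscosity_cp, out$trial), ]
  rownames(out) <- NULL
  class(out) <- c("trial_summary", "data.frame")
  attr(out, "truth") <- list(effects = effects, sd_individual = sd_individual,
                             sd_ind_position = sd_ind_position,
                             sd_resid = sd_resid, seed = seed)
  out
}
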