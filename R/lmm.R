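#' Fit the study's linear mixed-effects model to trial averages
#'
#' The inference stage: per-trial means are the observations; fixed effects
#' are viscosity and, when the variable was measured at several body
#' positions, position and (optionally, chosen by AIC on maximum-likelihood
#' fits) their interaction. Random intercepts: individual, with body point
#' nested in individual when positions are present. Residual variance may
#' differ by position (nlme's `varIdent` variance function). The F table
#' uses the conservative inner-outer (containment) denominator degrees of
#' freedom. The response can be log-transformed (used for Reynolds number);
#' estimated marginal means are then back-transformed with multiplicative
#' SEs.
#'
#' @param data a `trial_summary` data.frame (columns `individual`, `trial`,
#'   `viscosity_cp`, `body_position`, `variable`, `value`).
#' @param variable which variable to model (must match `data$variable`;
#'   `NULL` if the table holds a single unnamed variable).
#' @param interaction `"aic"` (include viscosity x position if it lowers ML
#'   AIC), `"always"`, or `"never"`.
#' @param heteroscedastic_by_position if `TRUE`, fit per-position residual
#'   variances (varIdent).
#' @param log_transform if `TRUE`, model `log(value)`.
#' @param alpha significance level for the connecting letters.
#' @return An object of class `swim_lmm` with components `fit` (the nlme
#'   fit), `f_table`, `emm_table`, `letters`, `r2` (marginal, conditional),
#'   `variance_components`, `singular` (logical flag), `interaction_used`.
#' @seealso [anova_df_conservative()], [pseudo_r2()], [pairwise_bonferroni()]
#' @export
swim_lmm <- function(data, variable = NULL,
                     interaction = c("aic", "always", "never"),
                     heteroscedastic_by_position = FALSE,
                     log_transform = FALSE, alpha = 0.05) {
  interaction <- match.arg(interaction)
  if (!is.null(variable)) {
    if (!variable %in% data$variable) stop("variable not present: ", variable)
    data <- data[data$variable == variable, ]
  }
  data <- data[!is.na(data$value), ]
  if (length(unique(data$individual)) < 2) {
    stop("at least two individuals are required to identify the random effect")
  }
  if (log_transform && any(data$value <= 0)) {
    stop("log transform requires strictly positive values")
  }
  d <- data.frame(
    individual = factor(data$individual),
    viscosity = factor(data$viscosity_cp),
    value = if (log_transform) log(data$value) else data$value)
  has_pos <- !all(is.na(data$body_position))
  if (has_pos) d$position <- factor(data$body_position)
  random <- if (has_pos) ~ 1 | individual / position else ~ 1 | individual
  weights <- if (heteroscedastic_by_position) {
    if (!has_pos) stop("heteroscedastic_by_position needs a position column")
    nlme::varIdent(form = ~ 1 | position)
  } else NULL
  use_int <- FALSE
  if (has_pos && interaction != "never") {
    if (interaction == "always") {
      use_int <- TRUE
    } else {
      a0 <- AIC(fit_lme(value ~ viscosity + position, d, random, weights, "ML"))
      a1 <- AIC(fit_lme(value ~ viscosity * position, d, random, weights, "ML"))
      use_int <- a1 < a0
    }
  }
  fixed <- if (!has_pos) value ~ viscosity else if (use_int)
    value ~ viscosity * position else value ~ viscosity + position
  fit <- fit_lme(fixed, d, random, weights, "REML")
  ftab <- anova(fit)
  terms <- rownames(ftab)[rownames(ftab) != "(Intercept)"]
  f_table <- data.frame(
    term = terms,
    F = ftab[terms, "F-value"],
    df_num = ftab[terms, "numDF"],
    df_den = ftab[terms, "denDF"],
    p = ftab[terms, "p-value"])
  rownames(f_table) <- NULL
  vc <- variance_components(fit, d)
  singular <- any(vc$random_sd < 1e-5 * max(vc$resid_sd, 1e-12))
  emm_tab <- emm_cells(fit, has_pos, log_transform)
  letters <- pairwise_bonferroni(fit, has_pos, log_transform, alpha = alpha)
  r2 <- pseudo_r2(fit, d)
  structure(list(
    fit = fit, f_table = f_table, emm_table = emm_tab,
    letters = letters, r2 = r2, variance_components = vc,
    singular = singular, interaction_used = if (has_pos) use_int else NA,
    log_transform = log_transform, has_position = has_pos,
    variable = variable %||% "value", data = d,
    call = match.call()), class = "swim_lmm")
}

fit_lme <- function(fixed, d, random, weights, method) {
  args <- list(fixed = fixed, data = d, random = random, method = method,
               control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                          msMaxIter = 200, returnObject = TRUE))
  if (!is.null(weights)) args$weights <- weights
  do.call(nlme::lme, args)
}

# Random-intercept SDs (per grouping level) and residual SD(s), including
# per-position residual SDs under varIdent.
variance_components <- function(fit, d) {
  vcs <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vcs[, "StdDev"]))
  labs <- rownames(vcs)
  random_sd <- sds[labs == "(Intercept)"]
  resid_sd <- fit$sigma
  strata <- NULL
  vf <- fit$modelStruct$varStruct
  if (!is.null(vf)) {
    w <- nlme::varWeights(vf)
    groups <- attr(vf, "groups")
    strata <- tapply(1 / w, groups, function(z) unique(round(z, 10))[1]) * resid_sd
  }
  list(random_sd = random_sd, resid_sd = resid_sd, resid_sd_by_stratum = strata)
}

#' Conservative (inner-outer) denominator degrees of freedom
#'
#' The containment counting rule for multilevel models: each fixed-effect
#' term is tested at the innermost grouping level at which it varies, with
#' denominator df `m_i - m_{i-1} - p_i`, where `m_i` counts groups at that
#' level (`m_0 = 1`, observations at the innermost), and `p_i` the fixed
#' coefficients estimated at the level. For the default trial-average
#' design (38 trials, 6 individuals) this gives viscosity df (3, 29) in a
#' viscosity-only model, and position df (2, 10) when three body positions
#' are nested in 6 individuals. With a single grouping level the rule
#' reduces to classical ANOVA df.
#'
#' @param design data.frame with one row per observation: columns
#'   `individual`, `viscosity_cp`, and optionally `body_position`.
#' @param interaction include the viscosity x position interaction term?
#' @return data.frame with `term`, `df_num`, `df_den`.
#' @export
anova_df_conservative <- function(design, interaction = FALSE) {
  n <- nrow(design)
  m1 <- length(unique(design$individual))
  v <- length(unique(design$viscosity_cp))
  has_pos <- "body_position" %in% names(design) &&
    !all(is.na(design$body_position))
  if (!has_pos) {
    out <- data.frame(term = "viscosity", df_num = v - 1,
                      df_den = n - m1 - (v - 1))
    return(out)
  }
  p <- length(unique(design$body_position))
  m2 <- nrow(unique(design[, c("individual", "body_position")]))
  p_obs <- (v - 1) + if (interaction) (v - 1) * (p - 1) else 0
  out <- data.frame(
    term = c("viscosity", "position"),
    df_num = c(v - 1, p - 1),
    df_den = c(n - m2 - p_obs, m2 - m1 - (p - 1)))
  if (interaction) {
    out <- rbind(out, data.frame(term = "viscosity:position",
                                 df_num = (v - 1) * (p - 1),
                                 df_den = n - m2 - p_obs))
  }
  out
}

#' Nakagawa-Schielzeth pseudo-R-squared for a mixed model
#'
#' Marginal R2 (fixed effects only) and conditional R2 (whole model):
#' `R2m = var_f / (var_f + var_r + var_e)` and
#' `R2c = (var_f + var_r) / (var_f + var_r + var_e)`, with `var_f` the
#' variance of the fixed-effect predictions, `var_r` the summed random
#' intercept variances and `var_e` the residual variance (averaged over
#' variance-function strata when present).
#'
#' @param fit an `nlme::lme` fit or a `swim_lmm` object.
#' @param data the model frame (taken from the object when missing).
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
pseudo_r2 <- function(fit, data = NULL) {
  if (inherits(fit, "swim_lmm")) {
    data <- data %||% fit$data
    fit <- fit$fit
  }
  var_f <- var(as.numeric(predict(fit, level = 0)))
  vc <- variance_components(fit, data)
  if (any(!is.finite(vc$random_sd)) || any(vc$random_sd < 0)) {
    stop("negative or undefined random-effect variance estimate")
  }
  var_r <- sum(vc$random_sd^2)
  var_e <- if (!is.null(vc$resid_sd_by_stratum)) {
    mean(vc$resid_sd_by_stratum^2)
  } else vc$resid_sd^2
  denom <- var_f + var_r + var_e
  c(r2_marginal = var_f / denom, r2_conditional = (var_f + var_r) / denom)
}

# Estimated marginal means over the fixed-effect grid, with model SEs;
# back-transformed (multiplicative SE) for log-scale models.
emm_cells <- function(fit, has_pos, log_transform) {
  spec <- if (has_pos) ~ viscosity * position else ~ viscosity
  em <- emmeans::emmeans(fit, spec, data = nlme::getData(fit))
  df <- as.data.frame(em)
  out <- data.frame(viscosity = df$viscosity)
  if (has_pos) out$position <- df$position
  if (log_transform) {
    out$mean <- exp(df$emmean)
    out$se_factor <- exp(df$SE)
  } else {
    out$mean <- df$emmean
    out$se <- df$SE
  }
  attr(out, "emmGrid") <- em
  out
}

#' Bonferroni-corrected pairwise comparisons with connecting letters
#'
#' The comparison family is the one the study reports: all pairs of
#' treatments within a body position plus all pairs of positions within a
#' treatment (just the treatment pairs when there is no position factor).
#' Raw p-values come from the estimated-marginal-means contrasts; each is
#' multiplied by the total family size m (capped at 1). Connecting letters
#' are assigned by the insert-and-absorb algorithm: cells sharing a letter
#' are not significantly different at `alpha` after correction. Cells are
#' lettered in order of their estimated marginal mean so reports are
#' reproducible.
#'
#' @param fit an `nlme::lme` fit or `swim_lmm` object.
#' @param has_pos does the model have a position factor? (inferred for
#'   `swim_lmm` input).
#' @param log_transform was the response log-transformed?
#' @param alpha significance level applied to adjusted p-values.
#' @return list with `comparisons` (all family comparisons, raw and
#'   adjusted p), `m` (family size), `letters_by_position` (viscosity
#'   letters within each position) and `letters_by_viscosity` (position
#'   letters within each viscosity; `NULL` without positions).
#' @export
pairwise_bonferroni <- function(fit, has_pos = NULL, log_transform = FALSE,
                                alpha = 0.05) {
  if (inherits(fit, "swim_lmm")) {
    has_pos <- fit$has_position
    log_transform <- fit$log_transform
    fit <- fit$fit
  }
  data <- nlme::getData(fit)
  if (is.null(has_pos)) has_pos <- "position" %in% names(data)
  if (has_pos) {
    em_vp <- emmeans::emmeans(fit, ~ viscosity | position, data = data)
    em_pv <- emmeans::emmeans(fit, ~ position | viscosity, data = data)
    c1 <- as.data.frame(emmeans::contrast(em_vp, "pairwise", adjust = "none"))
    c2 <- as.data.frame(emmeans::contrast(em_pv, "pairwise", adjust = "none"))
    c1$family <- "viscosity_within_position"
    c2$family <- "position_within_viscosity"
    names(c1)[names(c1) == "position"] <- "stratum"
    names(c2)[names(c2) == "viscosity"] <- "stratum"
    comp <- rbind(c1[, c("family", "stratum", "contrast", "estimate", "p.value")],
                  c2[, c("family", "stratum", "contrast", "estimate", "p.value")])
  } else {
    em <- emmeans::emmeans(fit, ~ viscosity, data = data)
    c1 <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
    comp <- data.frame(family = "viscosity", stratum = NA,
                       contrast = c1$contrast, estimate = c1$estimate,
                       p.value = c1$p.value)
  }
  m <- nrow(comp)
  comp$p_adj <- pmin(1, m * comp$p.value)
  letters_by_position <- letters_for(comp, "viscosity_within_position",
                                     if (has_pos) "viscosity" else NULL,
                                     fit, has_pos, alpha)
  letters_by_viscosity <- if (has_pos) {
    letters_for(comp, "position_within_viscosity", "position",
                fit, has_pos, alpha)
  } else NULL
  list(comparisons = comp, m = m,
       letters_by_position = letters_by_position,
       letters_by_viscosity = letters_by_viscosity)
}

# Letters for one family direction; strata = the conditioning factor values.
letters_for <- function(comp, family, what, fit, has_pos, alpha) {
  data <- nlme::getData(fit)
  if (!has_pos) {
    sub <- comp[comp$family == "viscosity", ]
    em <- as.data.frame(emmeans::emmeans(fit, ~ viscosity, data = data))
    lv <- as.character(em$viscosity)
    lt <- connecting_letters(lv, parse_pairs(sub$contrast, lv), sub$p_adj,
                             means = em$emmean, alpha = alpha)
    return(data.frame(viscosity = lv, letters = lt))
  }
  sub_all <- comp[comp$family == family, ]
  em <- as.data.frame(emmeans::emmeans(fit, ~ viscosity * position,
                                       data = data))
  out <- list()
  for (s in unique(sub_all$stratum)) {
    sub <- sub_all[sub_all$stratum == s, ]
    if (what == "viscosity") {
      cells <- em[em$position == s, ]
      lv <- as.character(cells$viscosity)
    } else {
      cells <- em[em$viscosity == s, ]
      lv <- as.character(cells$position)
    }
    lt <- connecting_letters(lv, parse_pairs(sub$contrast, lv), sub$p_adj,
                             means = cells$emmean, alpha = alpha)
    row <- data.frame(stratum = s, level = lv, letters = lt)
    names(row)[1:2] <- if (what == "viscosity") c("position", "viscosity") else
      c("viscosity", "position")
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

# emmeans writes contrasts as "viscosity1 - viscosity40"; recover the two
# level names robustly by matching against the known level set.
parse_pairs <- function(contrasts, levels) {
  lv <- levels[order(-nchar(levels))]
  t(vapply(strsplit(as.character(contrasts), " - ", fixed = TRUE),
           function(parts) {
    parts <- sub("^\\((.*)\\)$", "\\1", parts)  # emmeans wraps levels with "-"
    vapply(parts, function(p) {
      hit <- lv[vapply(lv, function(l) {
        p == l || endsWith(p, l) || startsWith(p, l)
      }, logical(1))]
      if (!length(hit)) stop("cannot match contrast label: ", p)
      hit[1]
    }, character(1))
  }, character(2)))
}

#' Connecting letters by insert-and-absorb
#'
#' Compact letter display: cells sharing a letter are not significantly
#' different. Starting from one group holding every cell, each significant
#' pair splits every group containing both members into two (insert), and
#' groups that are subsets of others are deleted (absorb). Letters are
#' assigned to groups ordered by the mean of their cells, so output is
#' invariant to cell relabeling.
#'
#' @param cells character vector of cell names.
#' @param pairs 2-column character matrix of compared pairs.
#' @param p_adj adjusted p-value per pair.
#' @param means cell means used only to order the letters (default:
#'   alphabetical).
#' @param alpha significance level.
#' @return character vector of letter strings, one per cell.
#' @export
connecting_letters <- function(cells, pairs, p_adj, means = NULL,
                               alpha = 0.05) {
  groups <- list(cells)
  sig <- which(p_adj < alpha)
  for (k in sig) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    # absorb: drop groups contained in another
    keep <- rep(TRUE, length(new_groups))
    for (i in seq_along(new_groups)) {
      for (j in seq_along(new_groups)) {
        if (i != j && keep[j] &&
            all(new_groups[[i]] %in% new_groups[[j]]) &&
            (length(new_groups[[i]]) < length(new_groups[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    groups <- new_groups[keep]
  }
  ord_val <- if (is.null(means)) seq_along(cells) else means
  grp_rank <- vapply(groups, function(g) min(ord_val[match(g, cells)]),
                     numeric(1))
  groups <- groups[order(grp_rank)]
  out <- vapply(cells, function(cl) {
    paste0(letters[which(vapply(groups, function(g) cl %in% g, logical(1)))],
           collapse = "")
  }, character(1))
  unname(out)
}

#' @export
print.swim_lmm <- function(x, ...) {
  cat(sprintf("<swim_lmm> %s%s\n", x$variable,
              if (x$log_transform) " (log scale)" else ""))
  if (x$singular) cat("  NOTE: near-singular random-effect fit\n")
  if (isTRUE(x$interaction_used)) cat("  interaction included (AIC)\n")
  cat("\nANOVA-type F table (conservative df):\n")
  print(transform(x$f_table, F = round(F, 2), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("\nR2m = %.3f, R2c = %.3f\n",
              x$r2["r2_marginal"], x$r2["r2_conditional"]))
  invisible(x)
}

#' @export
summary.swim_lmm <- function(object, ...) {
  print(object)
  cat("\nEstimated marginal means:\n")
  print(object$emm_table, row.names = FALSE)
  cat(sprintf("\nBonferroni family: m = %d comparisons\n", object$letters$m))
  if (!is.null(object$letters$letters_by_position)) {
    cat("\nLetters (viscosities compared within position):\n")
    print(object$letters$letters_by_position, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.swim_lmm <- function(object, ...) nlme::fixef(object$fit)

#' @export
predict.swim_lmm <- function(object, newdata = NULL, level = 0, ...) {
  p <- if (is.null(newdata)) predict(object$fit, level = level) else
    predict(object$fit, newdata = newdata, level = level)
  if (object$log_transform) exp(p) else p
}

#' @export
residuals.swim_lmm <- function(object, ...) residuals(object$fit, ...)

#' @export
anova.swim_lmm <- function(object, ...) object$f_table

#' @export
plot.swim_lmm <- function(x, ...) {
  em <- x$emm_table
  xs <- as.numeric(as.character(em$viscosity))
  graphics::plot(xs, em$mean, log = "x", pch = 19,
                 xlab = "viscosity (cP)", ylab = x$variable, ...)
  if ("se" %in% names(em)) {
    graphics::arrows(xs, em$mean - em$se, xs, em$mean + em$se,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
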