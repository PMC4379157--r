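# display rounding mirrors the published tables: one decimal for N lines,
# whole numbers for C lines, two decimals for subsidence
.display_round <- function(value, units) {
  ifelse(units == "kg C ha-1", round(value),
         ifelse(units == "cm yr-1", round(value, 2), round(value, 1)))
}

.ledger_labels <- c(
  uptake_0n = "Total N uptake (0N plots)",
  ndr = "  from residue",
  ndsw = "  from surface water",
  ndgw = "  from shallow groundwater",
  n_deposition = "  from atmospheric deposition",
  n_fixation = "  from biological N2 fixation",
  surface_peat_n = "Surface peat N",
  peat_total_n = "Peat N (total)",
  nmin_growing = "Growing-season peat N mineralization",
  residue_min_fallow = "Residue N mineralized, fallow",
  soil_no3_at_flooding = "Soil NO3-N at flooding",
  nmin_fallow = "Fallow-season peat N mineralization",
  nmin_total = "Annual peat N mineralization",
  c_mineralized = "Annual C mineralized",
  residue_c_input = "Annual C input from residue",
  net_c_loss = "Net C loss",
  subsidence = "Subsidence"
)

#' @export
print.n_budget <- function(x, ...) {
  led <- x$ledger
  cat("Annual peatland N budget -- site:", x$site$site, "\n")
  cat(sprintf("NUE = %.2f, deposition = %g, fixation = %g kg N ha-1 (SE mode: %s)\n\n",
              x$constants$nue, x$constants$n_deposition,
              x$constants$n_fixation, x$se_mode))
  disp <- data.frame(
    item = .ledger_labels[led$item],
    value = .display_round(led$value, led$units),
    se = ifelse(led$se > 0, format(.display_round(led$se, led$units)), ""),
    units = led$units
  )
  rownames(disp) <- NULL
  print(disp, right = FALSE)
  invisible(x)
}

#' @export
coef.n_budget <- function(object, ...) {
  stats::setNames(object$ledger$value, object$ledger$item)
}

#' @export
confint.n_budget <- function(object, parm, level = 0.95, ...) {
  led <- object$ledger
  if (!missing(parm)) led <- led[led$item %in% parm, ]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(led$value - z * led$se, led$value + z * led$se)
  dimnames(out) <- list(led$item,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' Summary of a fitted N budget
#'
#' @param object an `"n_budget"` fit.
#' @param ... unused.
#' @return a `"summary.n_budget"` object: the ledger plus source shares of
#'   total uptake and the NUE-sensitivity range.
#' @export
summary.n_budget <- function(object, ...) {
  q <- object$quantities
  up <- q$uptake_0n$value
  shares <- 100 * c(residue = q$ndr$value, surface_water = q$ndsw$value,
                    groundwater = q$ndgw$value,
                    deposition = q$n_deposition$value,
                    fixation = q$n_fixation$value,
                    surface_peat = q$surface_peat_n$value) / up
  structure(list(fit = object, uptake_shares_pct = shares,
                 sensitivity = object$sensitivity),
            class = "summary.n_budget")
}

#' @export
print.summary.n_budget <- function(x, ...) {
  print(x$fit)
  cat("\nShare of total N uptake (%):\n")
  print(round(x$uptake_shares_pct, 1))
  sen <- x$sensitivity
  cat(sprintf("\nNUE sensitivity: net C loss %d (NUE %.2f) to %d (NUE %.2f) kg C ha-1\n",
              round(max(sen$net_c_loss)), sen$nue[which.max(sen$net_c_loss)],
              round(min(sen$net_c_loss)), sen$nue[which.min(sen$net_c_loss)]))
  invisible(x)
}

#' Re-evaluate the budget endpoints at new NUE values
#'
#' @param object an `"n_budget"` fit.
#' @param nue NUE values (fractions in (0, 1]); defaults to the fitted
#'   value.
#' @param ... unused.
#' @return data frame as in [nue_sensitivity()].
#' @export
predict.n_budget <- function(object, nue = object$constants$nue, ...) {
  nue_sensitivity(object, nue_grid = nue)
}

#' Plot the NUE-sensitivity curve
#'
#' Net soil C loss against the assumed N uptake efficiency, with +/- 1 SE
#' error bars.
#'
#' @param x an `"n_budget"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.n_budget <- function(x, ...) {
  sen <- x$sensitivity
  graphics::plot(sen$nue, sen$net_c_loss, type = "b", pch = 19,
                 xlab = "N uptake efficiency (fraction)",
                 ylab = expression("Net soil C loss (kg C " * ha^-1 *
                                     " " * yr^-1 * ")"),
                 main = paste("Site", x$site$site),
                 ylim = range(sen$net_c_loss - sen$net_c_loss_se,
                              sen$net_c_loss + sen$net_c_loss_se), ...)
  graphics::arrows(sen$nue, sen$net_c_loss - sen$net_c_loss_se,
                   sen$nue, sen$net_c_loss + sen$net_c_loss_se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$constants$nue, lty = 3)
  invisible(x)
}

#' Monte-Carlo draws from a fitted budget
#'
#' Draws every measured input from Normal(value, SE) and re-runs the
#' deterministic budget chain per draw — the stochastic twin of the
#' analytic propagation.  See [monte_carlo_budget()] for summaries.
#'
#' @param object an `"n_budget"` fit.
#' @param nsim number of draws.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @param truncate_negative truncate physically-negative draws
#'   (concentrations, uptakes) at zero.  Off by default to preserve SE
#'   fidelity; truncated draws are counted in a warning.
#' @param ... unused.
#' @return data frame, one row per draw, one column per derived ledger
#'   line; `seed` is stored as an attribute.
#' @export
simulate.n_budget <- function(object, nsim = 1, seed = NULL,
                              truncate_negative = FALSE, ...) {
  draws <- .mc_draws(object$site, object$constants, n_draws = nsim,
                     seed = seed, truncate_negative = truncate_negative)
  attr(draws, "seed") <- seed
  draws
}
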