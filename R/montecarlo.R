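# draw the measured inputs and push them through the budget chain.
# Returns a data.frame with one row per draw.
.mc_draws <- function(site, consts, n_draws, seed = NULL,
                      truncate_negative = FALSE, cn_se = 0) {
  if (!is.null(seed)) set.seed(seed)
  rq <- function(q) stats::rnorm(n_draws, q$value, q$se)
  v <- list(uptake_0n = rq(site$uptake_0n), ndr = rq(site$ndr),
            ndsw = rq(site$ndsw), ndgw = rq(site$ndgw),
            residue_n_fall = rq(site$residue_n_fall),
            residue_n_spring = rq(site$residue_n_spring),
            soil_no3 = rq(site$soil_no3_at_flooding),
            residue_c = rq(site$residue_c_input),
            cn_ratio = stats::rnorm(n_draws, site$profile$cn_ratio, cn_se))
  if (truncate_negative) {
    n_trunc <- sum(vapply(v, function(x) sum(x < 0), numeric(1)))
    if (n_trunc > 0)
      warning(n_trunc, " negative draw(s) truncated at 0", call. = FALSE)
    v <- lapply(v, pmax, 0)
  }
  out <- .budget_chain(v, consts, site$profile)
  as.data.frame(c(v[c("uptake_0n", "ndr", "ndsw", "ndgw")], out))
}

#' Monte-Carlo validation of the analytic error propagation
#'
#' Draws each measured input independently from Normal(value, SE), runs
#' the full deterministic budget per draw, and summarises every derived
#' ledger line.  On the strictly linear chain (fixed NUE and C:N) the
#' Monte-Carlo standard deviation converges to the analytic
#' root-sum-of-squares SE; for nonlinear extensions (uncertain C:N via
#' `cn_se`) the Monte-Carlo summaries are the authoritative uncertainty.
#'
#' @param site a [site_measurements()] object.
#' @param constants a [budget_constants()].
#' @param n_draws number of draws (default 10000).
#' @param seed integer seed (default 1432); runs are deterministic given
#'   the seed.
#' @param truncate_negative truncate physically-negative draws at zero
#'   (off by default so the Monte-Carlo sd matches the untruncated
#'   analytic propagation; truncation is a sensitivity option).
#' @param cn_se optional standard error attached to the soil C:N ratio
#'   (the analytic path treats C:N as exact).
#' @return object of class `"mc_budget"`: a data frame with one row per
#'   ledger line and columns `mean`, `sd`, `q2.5`, `q97.5`, plus the
#'   matching analytic `value`/`se` columns for comparison.  The raw
#'   draws are attached as attribute `"draws"`.
#' @examples
#' mc <- monte_carlo_budget(twitchell_site(1), n_draws = 2000, seed = 7)
#' mc[c("net_c_loss", "subsidence"), ]
#' @export
monte_carlo_budget <- function(site, constants = budget_constants(),
                               n_draws = 10000, seed = 1432,
                               truncate_negative = FALSE, cn_se = 0) {
  stopifnot(inherits(site, "site_measurements"))
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  draws <- .mc_draws(site, constants, n_draws, seed = seed,
                     truncate_negative = truncate_negative, cn_se = cn_se)
  # the draw chain lets the groundwater term cancel out of the peat total
  # exactly as the algebra does, so the matching analytic reference is the
  # single-counted ("consistent") propagation
  fit <- n_budget(site, constants, se_mode = "consistent")
  led <- fit$ledger
  keep <- intersect(names(draws), led$item)
  summ <- data.frame(
    item = keep,
    mean = vapply(draws[keep], mean, numeric(1)),
    sd = vapply(draws[keep], stats::sd, numeric(1)),
    q2.5 = vapply(draws[keep], stats::quantile, numeric(1), probs = 0.025),
    q97.5 = vapply(draws[keep], stats::quantile, numeric(1), probs = 0.975),
    value = led$value[match(keep, led$item)],
    se = led$se[match(keep, led$item)],
    row.names = keep
  )
  attr(summ, "draws") <- draws
  attr(summ, "n_draws") <- n_draws
  attr(summ, "seed") <- seed
  class(summ) <- c("mc_budget", "data.frame")
  summ
}

#' @export
print.mc_budget <- function(x, digits = 4, ...) {
  cat("Monte-Carlo budget:", attr(x, "n_draws"), "draws, seed",
      attr(x, "seed"), "\n")
  print.data.frame(x[, c("mean", "sd", "q2.5", "q97.5", "value", "se")],
                   digits = digits, ...)
  invisible(x)
}
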