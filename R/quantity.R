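#' Measured quantity with a standard error
#'
#' The universal currency of the budget: a scalar value in declared units
#' together with its standard error.  Every ledger line, measured input and
#' derived estimate in the package is a `quantity`; sums, differences and
#' exact-factor scalings propagate the SE by the root-sum-of-squares rule
#' (see [q_combine()] and [q_scale()]).
#'
#' @param value numeric scalar, the measured or derived value.
#' @param se numeric scalar, its standard error (>= 0).  Exact constants
#'   (unit conversions, literature values used as fixed assumptions) carry
#'   `se = 0`.
#' @param units unit tag, e.g. `"kg N ha-1"`, `"kg C ha-1"`, `"mg N L-1"`,
#'   `"cm yr-1"`, `"%"` or `""` for dimensionless.  Sums and differences
#'   require matching tags.
#' @return an object of class `"quantity"`.
#' @examples
#' uptake <- quantity(185, 10, "kg N ha-1")
#' gw     <- quantity(61.7, 9, "kg N ha-1")
#' uptake - gw
#' @export
quantity <- function(value, se = 0, units = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (se < 0) stop("standard error must be >= 0", call. = FALSE)
  structure(list(value = as.numeric(value), se = as.numeric(se),
                 units = as.character(units)),
            class = "quantity")
}

#' @export
print.quantity <- function(x, digits = 4, ...) {
  cat(format(x$value, digits = digits), "+/-", format(x$se, digits = digits),
      if (nzchar(x$units)) x$units else "", "\n")
  invisible(x)
}

is_quantity <- function(x) inherits(x, "quantity")

as_quantity <- function(x, units = "") {
  if (is_quantity(x)) x else quantity(x, 0, units)
}

#' Signed sum of quantities with SE propagation
#'
#' Combines quantities as `sum(signs * values)`; the standard error is the
#' root sum of squares of the component SEs, the propagation rule for sums
#' and differences of independent measurements.
#'
#' @param ... `quantity` objects (or bare numerics, treated as exact).
#' @param signs integer vector of +1/-1, recycled; default all +1.
#' @return a `quantity` in the common units.
#' @examples
#' q_combine(quantity(10, 3), quantity(5, 4), signs = c(1, -1)) # 5 +/- 5
#' @export
q_combine <- function(..., signs = NULL) {
  qs <- list(...)
  if (length(qs) == 1L && is.list(qs[[1]]) && !is_quantity(qs[[1]]))
    qs <- qs[[1]]
  if (!length(qs)) stop("no quantities to combine", call. = FALSE)
  units <- unique(vapply(qs, function(q) as_quantity(q)$units, character(1)))
  units <- setdiff(units, "")
  if (length(units) > 1L)
    stop("unit mismatch in q_combine(): ", paste(units, collapse = " vs "),
         call. = FALSE)
  if (is.null(signs)) signs <- rep(1, length(qs))
  signs <- rep_len(signs, length(qs))
  vals <- vapply(qs, function(q) as_quantity(q)$value, numeric(1))
  ses  <- vapply(qs, function(q) as_quantity(q)$se, numeric(1))
  quantity(sum(signs * vals), sqrt(sum(ses^2)),
           if (length(units)) units else "")
}

#' Scale a quantity by an exact factor
#'
#' Multiplying or dividing by an exact number (a unit conversion, a fixed
#' efficiency, a stoichiometric ratio) scales the value by the factor and
#' the SE by its absolute value.
#'
#' @param q a `quantity`.
#' @param factor finite numeric scalar.
#' @param units optional new unit tag (e.g. after a N-to-C conversion);
#'   defaults to the input tag.
#' @return a `quantity`.
#' @export
q_scale <- function(q, factor, units = q$units) {
  stopifnot(is_quantity(q), is.numeric(factor), length(factor) == 1L,
            is.finite(factor))
  quantity(q$value * factor, q$se * abs(factor), units)
}

#' @export
Ops.quantity <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(q_scale(e1, -1))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for quantities", call. = FALSE)
  }
  switch(.Generic,
    "+" = ,
    "-" = {
      sgn <- if (.Generic == "-") c(1, -1) else c(1, 1)
      q_combine(e1, e2, signs = sgn)
    },
    "*" = {
      if (is_quantity(e1) && is_quantity(e2))
        stop("product of two uncertain quantities is not supported; ",
             "use the Monte-Carlo path", call. = FALSE)
      if (is_quantity(e1)) q_scale(e1, e2) else q_scale(e2, e1)
    },
    "/" = {
      if (is_quantity(e2))
        stop("division by an uncertain quantity is not supported; ",
             "use the Monte-Carlo path", call. = FALSE)
      q_scale(e1, 1 / e2)
    },
    stop(.Generic, " not defined for quantities", call. = FALSE)
  )
}

#' Mean and standard error of replicate measurements
#'
#' Summarises plot- or replicate-level measurements as mean and standard
#' error of the mean (`sd/sqrt(n)`), the form in which all field
#' measurements enter the budget.
#'
#' @param values numeric vector of replicate measurements.
#' @param units unit tag for the result.
#' @return a `quantity`; a single replicate yields `se = 0` with a warning.
#' @examples
#' replicate_stats(c(1, 2, 3, 4)) # 2.5 +/- 0.6455
#' @export
replicate_stats <- function(values, units = "") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no replicate values", call. = FALSE)
  if (n == 1L) {
    warning("single replicate: standard error set to 0", call. = FALSE)
    return(quantity(values, 0, units))
  }
  quantity(mean(values), stats::sd(values) / sqrt(n), units)
}
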