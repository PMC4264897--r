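# Per-individual condition scores: scaled mass index, standardized residual
# index, and size-standardized body components.

#' Scaling constants for the scaled mass index
#'
#' @param b_sma positive scaling exponent (SMA slope of ln mass on ln length).
#' @param L0 positive reference length (mm), conventionally the arithmetic
#'   mean length of the reference population.
#' @param source free text recording where the constants came from.
#' @return a list of class `scaling_constants`.
#' @export
scaling_constants <- function(b_sma, L0, source = "user") {
  stopifnot(is.numeric(b_sma), length(b_sma) == 1, b_sma > 0,
            is.numeric(L0), length(L0) == 1, L0 > 0)
  structure(list(b_sma = b_sma, L0 = L0, source = source),
            class = "scaling_constants")
}

#' Reference length: arithmetic mean of the raw lengths
#'
#' @param data a `morph_data` data frame.
#' @param length_field which length column to average.
#' @param strict drop flagged rows first?
#' @return the mean raw (not log) length.
#' @export
reference_length <- function(data, length_field = "pronotum", strict = FALSE) {
  data <- apply_strict(data, strict)
  mean(data[[length_field]], na.rm = TRUE)
}

#' Scaled mass index
#'
#' Standardizes each animal's body mass to the mass it would have at the
#' reference length `L0`, given the allometric scaling exponent `b_sma`:
#' `smi_i = M_i * (L0 / L_i)^b_sma`.  Records with a non-positive length are
#' excluded with a warning.
#'
#' @param data a `morph_data` data frame.
#' @param b_sma scaling exponent, or a [scaling_constants()] object (in which
#'   case `L0` is taken from it too).
#' @param L0 reference length (mm); defaults to the arithmetic mean length of
#'   `data` itself.
#' @param length_field length column to standardize against.
#' @param mass_field mass column to standardize (fresh mass by default).
#' @param strict drop flagged rows?
#' @return a data frame of class `condition_scores` with columns `id` and
#'   `smi` (g), carrying the constants used as attributes `b_sma` and `L0`.
#' @export
scaled_mass_index <- function(data, b_sma, L0 = NULL,
                              length_field = "pronotum",
                              mass_field = "fresh_mass", strict = FALSE) {
  if (inherits(b_sma, "scaling_constants")) {
    L0 <- b_sma$L0
    b_sma <- b_sma$b_sma
  }
  stopifnot(b_sma > 0)
  data <- apply_strict(data, strict)
  L <- data[[length_field]]
  M <- data[[mass_field]]
  if (is.null(L0)) L0 <- mean(L[L > 0], na.rm = TRUE)
  stopifnot(L0 > 0)
  ok <- !is.na(L) & !is.na(M) & L > 0
  if (any(!ok))
    warning(sum(!ok), " records excluded from SMI (missing or non-positive values)")
  out <- data.frame(id = data$id[ok],
                    smi = M[ok] * (L0 / L[ok])^b_sma,
                    row.names = NULL)
  attr(out, "b_sma") <- b_sma
  attr(out, "L0") <- L0
  attr(out, "length_field") <- length_field
  class(out) <- c("condition_scores", "data.frame")
  out
}

#' Standardized residual condition index
#'
#' Regresses ln mass on ln length by OLS over the whole dataset (a common
#' slope across any groups) and returns each animal's raw residual divided
#' by the residual standard deviation `sqrt(RSS / (n - 2))`.  With this
#' standardization the scores have mean zero and root mean square one
#' (computed with denominator `n - 2`).  A leverage-adjusted (internally
#' studentized) variant is available behind `studentized = TRUE`.
#'
#' @param data a `morph_data` data frame.
#' @param length_field,mass_field columns to regress.
#' @param studentized use leverage-adjusted standardized residuals instead of
#'   the plain residual / residual-SD convention.
#' @param strict drop flagged rows?
#' @return a `condition_scores` data frame with columns `id` and
#'   `residual_index`; the fitted slope and intercept are attached as
#'   attributes `slope` and `intercept`.
#' @export
residual_index <- function(data, length_field = "pronotum",
                           mass_field = "fresh_mass",
                           studentized = FALSE, strict = FALSE) {
  data <- apply_strict(data, strict)
  L <- data[[length_field]]
  M <- data[[mass_field]]
  ok <- !is.na(L) & !is.na(M) & L > 0 & M > 0
  if (sum(ok) < 3) stop("need at least 3 usable records")
  if (any(!ok))
    warning(sum(!ok), " records excluded from residual index")
  x <- log(L[ok]); y <- log(M[ok])
  if (stats::var(x) == 0) stop("degenerate regression: zero length variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  n <- length(res)
  if (rss < n * .Machine$double.eps^0.9) {
    scores <- rep(0, n)                     # perfectly collinear data
  } else if (isTRUE(studentized)) {
    scores <- stats::rstandard(fit)
  } else {
    scores <- res / sqrt(rss / (n - 2))
  }
  out <- data.frame(id = data$id[ok], residual_index = unname(scores),
                    row.names = NULL)
  attr(out, "slope") <- unname(stats::coef(fit)[2L])
  attr(out, "intercept") <- unname(stats::coef(fit)[1L])
  attr(out, "length_field") <- length_field
  class(out) <- c("condition_scores", "data.frame")
  out
}

#' Size-standardized body component mass
#'
#' Applies the scaled-mass-index transformation to a body component (dry,
#' lean dry, water or fat mass): `comp_i * (L0 / L_i)^b`.  The exponent is,
#' by default, the component's own SMA slope against length
#' (`exponent_policy = "component_specific"`), refit on the records where the
#' component is positive; alternatively the body-mass exponent can be reused
#' (`exponent_policy = "body_mass"`, requires `b_sma`).  `L0` is the same
#' reference length used for the scaled body mass.
#'
#' @param data a `morph_data` data frame.
#' @param component one of `"dry_mass"`, `"lean_dry_mass"`, `"water_mass"`,
#'   `"fat_mass"` (or any numeric column).
#' @param L0 reference length; defaults to the mean length of `data`.
#' @param length_field length column.
#' @param exponent_policy `"component_specific"` (default) or `"body_mass"`.
#' @param b_sma body-mass exponent, required when
#'   `exponent_policy = "body_mass"`.
#' @param strict drop flagged rows?
#' @return a `condition_scores` data frame with columns `id` and `scaled`
#'   plus attributes `component` and `exponent`.
#' @export
scale_component <- function(data, component, L0 = NULL,
                            length_field = "pronotum",
                            exponent_policy = c("component_specific", "body_mass"),
                            b_sma = NULL, strict = FALSE) {
  exponent_policy <- match.arg(exponent_policy)
  if (!component %in% names(data))
    stop("component `", component, "` not present in data")
  data <- apply_strict(data, strict)
  L <- data[[length_field]]
  comp <- data[[component]]
  ok <- !is.na(L) & !is.na(comp) & L > 0 & comp > 0
  if (any(!ok))
    warning(sum(!ok), " records excluded from scaled ", component,
            " (missing or non-positive values)")
  if (sum(ok) < 3) stop("need at least 3 usable records for ", component)
  if (is.null(L0)) L0 <- mean(L[L > 0], na.rm = TRUE)
  if (exponent_policy == "component_specific") {
    b <- fit_sma(log(L[ok]), log(comp[ok]))$slope
  } else {
    if (is.null(b_sma)) stop("b_sma required for exponent_policy = \"body_mass\"")
    b <- b_sma
  }
  out <- data.frame(id = data$id[ok],
                    scaled = comp[ok] * (L0 / L[ok])^b,
                    row.names = NULL)
  attr(out, "component") <- component
  attr(out, "exponent") <- b
  attr(out, "L0") <- L0
  class(out) <- c("condition_scores", "data.frame")
  out
}
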