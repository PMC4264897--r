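# Three-way comparison of condition-assessment methods on a two-factor
# design: ANOVA on scaled-mass-index scores, ANOVA on residual-index scores,
# and ANCOVA on log mass with log length as covariate.

.check_two_factors <- function(sex, diet) {
  sex <- droplevels(factor(sex))
  diet <- droplevels(factor(diet))
  if (nlevels(sex) != 2 || nlevels(diet) != 2)
    stop("both factors must be binary")
  cells <- table(sex, diet)
  if (any(cells < 2)) stop("every sex x diet cell needs at least 2 records")
  list(sex = sex, diet = diet)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each value from its group
#' center: the mean by default (classic Levene) or the median
#' (Brown-Forsythe).  Delegates to [car::leveneTest()].
#'
#' @param values numeric scores.
#' @param group grouping factor (two or more groups, each with n >= 2).
#' @param center `"mean"` (default) or `"median"`.
#' @return a list with `statistic` (W), `df` (numerator, denominator),
#'   `p_value` and `center`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- droplevels(factor(group))
  if (nlevels(g) < 2) stop("at least two groups required")
  if (min(table(g)) < 2) stop("each group needs at least 2 values")
  lt <- car::leveneTest(values, g,
                        center = if (center == "mean") base::mean else stats::median)
  W <- lt[1, "F value"]
  p <- lt[1, "Pr(>F)"]
  if (!is.finite(W)) { W <- 0; p <- 1 }   # all deviations zero
  list(test = "levene", statistic = unname(W),
       df = c(lt$Df[1], lt$Df[2]), p_value = unname(p), center = center)
}

#' Two-way ANOVA on condition scores
#'
#' Additive two-way ANOVA (no interaction) of per-individual condition
#' scores on two binary factors, with Type II sums of squares -- for an
#' additive model these are the [stats::drop1()] partial F tests, and on a
#' balanced design they coincide with the sequential (Type I) sums of
#' squares.  Levene's test is run within each factor and reported as an
#' assumption flag.
#'
#' @param scores numeric condition scores (one per individual).
#' @param sex,diet binary factors aligned with `scores`.
#' @param alpha level for the Levene flag.
#' @param method_label label recorded in the `method` column.
#' @return a data frame with one row per factor: `method, factor_name, F,
#'   df1, df2, p, levene_W, levene_p, levene_violated,
#'   slopes_heterogeneous` (always `NA` here; the column exists so method
#'   reports can be stacked).
#' @export
anova_index <- function(scores, sex, diet, alpha = 0.05,
                        method_label = "index_anova") {
  fx <- .check_two_factors(sex, diet)
  stopifnot(length(scores) == length(fx$sex))
  dat <- data.frame(score = scores, sex = fx$sex, diet = fx$diet)
  fit <- stats::lm(score ~ sex + diet, data = dat)
  dr <- stats::drop1(fit, test = "F")
  lev <- list(sex = levene_test(scores, fx$sex),
              diet = levene_test(scores, fx$diet))
  out <- do.call(rbind, lapply(c("sex", "diet"), function(f) {
    data.frame(method = method_label, factor_name = f,
               F = dr[f, "F value"], df1 = dr[f, "Df"],
               df2 = fit$df.residual, p = dr[f, "Pr(>F)"],
               levene_W = lev[[f]]$statistic, levene_p = lev[[f]]$p_value,
               levene_violated = lev[[f]]$p_value < alpha,
               slopes_heterogeneous = NA,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ANCOVA of log body mass with a log length covariate
#'
#' Fits `ln mass ~ sex + diet + ln length + sex:ln length + diet:ln length`,
#' tests the homogeneity-of-slopes assumption through the two interaction
#' terms (partial F tests at `alpha = 0.05`, the conventional removal
#' threshold), removes them when non-significant, and reports the additive
#' model's Type II F tests for the factors.  If either interaction is
#' significant the slopes are heterogeneous: the additive model is still
#' reported, with `slopes_heterogeneous = TRUE` and a warning, since the
#' adjusted means are then size-dependent.
#'
#' A zero-variance covariate (all lengths equal) is dropped with a warning,
#' in which case the analysis reduces exactly to the two-way ANOVA on log
#' mass.
#'
#' @param data a `morph_data` data frame with `sex` and `diet` columns.
#' @param length_field,mass_field columns used for the covariate and response.
#' @param alpha interaction-removal and flag threshold.
#' @param strict drop flagged rows?
#' @return a data frame shaped like [anova_index()]'s output
#'   (`method = "ancova"`), with the interaction p-values attached as
#'   attribute `interaction_p`.
#' @export
ancova_mass <- function(data, length_field = "pronotum",
                        mass_field = "fresh_mass", alpha = 0.05,
                        strict = FALSE) {
  data <- apply_strict(data, strict)
  fx <- .check_two_factors(data$sex, data$diet)
  dat <- data.frame(lnM = log(data[[mass_field]]),
                    lnL = log(data[[length_field]]),
                    sex = fx$sex, diet = fx$diet)
  if (any(!is.finite(dat$lnM)) || any(!is.finite(dat$lnL)))
    stop("mass and length must be positive for the log-scale ANCOVA")

  int_p <- c(sex = NA_real_, diet = NA_real_)
  het <- FALSE
  if (stats::var(dat$lnL) == 0) {
    warning("covariate has zero variance; reducing to a two-way ANOVA on log mass")
    red <- stats::lm(lnM ~ sex + diet, data = dat)
  } else {
    full <- stats::lm(lnM ~ sex + diet + lnL + sex:lnL + diet:lnL, data = dat)
    dint <- stats::drop1(full, test = "F")
    int_p <- c(sex = dint["sex:lnL", "Pr(>F)"], diet = dint["diet:lnL", "Pr(>F)"])
    het <- any(int_p < alpha)
    if (het)
      warning("heterogeneous slopes (interaction p < ", alpha,
              "); adjusted means from the additive model are size-dependent")
    red <- stats::lm(lnM ~ sex + diet + lnL, data = dat)
  }
  dr <- stats::drop1(red, test = "F")
  out <- do.call(rbind, lapply(c("sex", "diet"), function(f) {
    data.frame(method = "ancova", factor_name = f,
               F = dr[f, "F value"], df1 = dr[f, "Df"],
               df2 = red$df.residual, p = dr[f, "Pr(>F)"],
               levene_W = NA_real_, levene_p = NA_real_,
               levene_violated = NA, slopes_heterogeneous = het,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "interaction_p") <- int_p
  out
}

#' Compare three condition-assessment methods on a factorial design
#'
#' The machine-readable twin of a method-comparison table: runs (1) ANOVA on
#' scaled-mass-index scores computed with the supplied reference constants,
#' (2) ANOVA on standardized residual-index scores from the dataset's own
#' pooled OLS fit, and (3) ANCOVA on log mass with log length covariate, and
#' stacks the factor effects with their assumption flags.
#'
#' @param data a `morph_data` data frame with `sex` and `diet` factors.
#' @param b_sma scaling exponent for the scaled mass index (typically from a
#'   reference population), or a [scaling_constants()] object.
#' @param L0 reference length; defaults to the mean length of `data`.
#' @param length_field length column.
#' @param alpha significance level used by the pre-tests and flags.
#' @param strict drop flagged rows?
#' @return a data frame with one row per method x factor: `method`
#'   (`smi_anova`, `residual_anova`, `ancova`), `factor_name`, `F`, `df1`,
#'   `df2`, `p` and assumption flags.
#' @export
compare_methods <- function(data, b_sma, L0 = NULL, length_field = "pronotum",
                            alpha = 0.05, strict = FALSE) {
  data <- apply_strict(data, strict)
  if (!all(c("sex", "diet") %in% names(data)))
    stop("data must carry sex and diet factors")
  smi <- scaled_mass_index(data, b_sma, L0, length_field = length_field)
  ri <- residual_index(data, length_field = length_field)
  m_smi <- match(data$id, smi$id)
  m_ri <- match(data$id, ri$id)
  if (anyNA(m_smi) || anyNA(m_ri))
    stop("scores could not be computed for every record; ",
         "resolve flagged/non-positive rows first")
  rows_smi <- anova_index(smi$smi[m_smi], data$sex, data$diet, alpha = alpha,
                          method_label = "smi_anova")
  rows_ri <- anova_index(ri$residual_index[m_ri], data$sex, data$diet,
                         alpha = alpha, method_label = "residual_anova")
  rows_anc <- ancova_mass(data, length_field = length_field, alpha = alpha)
  out <- rbind(rows_smi, rows_ri, rows_anc)
  attr(out, "constants") <- list(b_sma = attr(smi, "b_sma"),
                                 L0 = attr(smi, "L0"),
                                 residual_slope = attr(ri, "slope"))
  out
}
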