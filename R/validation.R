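# Correlation machinery for validating condition indices against body
# composition: component-vs-size tables and index-vs-scaled-component tables.

#' Pearson product-moment correlation with t test
#'
#' Thin wrapper around [stats::cor.test()] that returns a flat result row.
#' Zero-variance input yields an explicit "undefined" result (`r = NA`)
#' rather than an error, so correlation tables keep a stable shape.
#'
#' @param x,y numeric vectors.
#' @return a list with `r`, `n`, `t`, `df`, `p_value`.
#' @export
pearson_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  near_const <- function(v)
    stats::sd(v) <= 1e-12 * max(1, abs(mean(v)))
  if (n < 3 || near_const(x) || near_const(y))
    return(list(r = NA_real_, n = n, t = NA_real_, df = max(n - 2, 0),
                p_value = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tstat <- unname(ct$statistic)
  p <- ct$p.value
  if (abs(r) >= 1) { tstat <- Inf * sign(r); p <- 0 }
  list(r = r, n = n, t = tstat, df = unname(ct$parameter), p_value = p)
}

.cor_row <- function(table, component, size_or_index, group, x, y, alpha) {
  pc <- pearson_cor(x, y)
  data.frame(table = table, component = component,
             size_or_index = size_or_index, group = group,
             r = pc$r, n = pc$n, t = pc$t, p = pc$p_value,
             significant = if (is.na(pc$p_value)) NA else pc$p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Correlations of body components with body size measures
#'
#' Builds the full cross of component (absolute and, optionally, relative
#' percentage form) by size measure by group.  Relative components are the
#' component as a percentage of fresh body mass ([relative_component()]).
#' Size measures absent from the data are skipped with a warning, so species
#' lacking e.g. tibia or femur measurements still produce a table.
#'
#' @param data a `morph_data` data frame.
#' @param components component columns to use (defaults to the four mass
#'   components).
#' @param size_measures size columns to correlate against.
#' @param by_sex also emit per-sex rows (requires a `sex` column)?
#' @param pooled emit pooled rows?
#' @param include_relative also emit the percentage forms?
#' @param alpha two-sided significance level for the `significant` flag
#'   (no multiple-testing correction by default).
#' @param p_adjust optional p-adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"holm"`); `"none"` by default.
#' @param strict drop flagged rows?
#' @return a data frame with one row per component x size x group, columns
#'   `table, component, size_or_index, group, r, n, t, p, significant`.
#' @export
component_size_table <- function(data,
                                 components = c("dry_mass", "fat_mass",
                                                "lean_dry_mass", "water_mass"),
                                 size_measures = c("fresh_mass", "pronotum",
                                                   "tibia", "femur"),
                                 by_sex = TRUE, pooled = TRUE,
                                 include_relative = TRUE, alpha = 0.05,
                                 p_adjust = "none", strict = FALSE) {
  data <- apply_strict(data, strict)
  absent <- setdiff(c(components, size_measures), names(data))
  if (length(absent))
    warning("skipping absent fields: ", paste(absent, collapse = ", "))
  components <- intersect(components, names(data))
  size_measures <- intersect(size_measures, names(data))
  groups <- character(0)
  if (pooled) groups <- "pooled"
  if (by_sex && "sex" %in% names(data))
    groups <- c(groups, levels(droplevels(factor(data$sex))))
  rows <- list()
  for (comp in components) {
    forms <- list(abs = data[[comp]])
    labels <- comp
    if (include_relative) {
      forms$rel <- relative_component(data[[comp]], data$fresh_mass)
      labels <- c(labels, paste0("pct_", comp))
    }
    for (k in seq_along(forms)) {
      for (sz in size_measures) {
        for (grp in groups) {
          sel <- if (grp == "pooled") rep(TRUE, nrow(data)) else data$sex == grp
          rows[[length(rows) + 1L]] <-
            .cor_row("component_size", labels[k], sz, grp,
                     forms[[k]][sel], data[[sz]][sel], alpha)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
    out$significant <- ifelse(is.na(out$p), NA, out$p < alpha)
  }
  out
}

#' Correlations of condition indices with scaled body components
#'
#' Correlates each condition index (scaled mass index and/or residual index)
#' against each size-standardized component, per group and pooled.  The
#' score tables must cover the same individuals; ids are aligned explicitly
#' and a mismatch is an error.
#'
#' @param indices data frame with an `id` column and one column per index
#'   (any of `smi`, `residual_index`).
#' @param scaled named list of `condition_scores` tables from
#'   [scale_component()] (names are used as component labels), or a single
#'   data frame with `id` plus one column per scaled component.
#' @param sex optional per-individual factor (aligned to `indices$id`) for
#'   per-group rows.
#' @param alpha significance level for the flag.
#' @return a data frame shaped like [component_size_table()]'s output with
#'   `table = "index_component"`.
#' @export
index_component_table <- function(indices, scaled, sex = NULL, alpha = 0.05) {
  idx_cols <- intersect(c("smi", "residual_index"), names(indices))
  if (!length(idx_cols)) stop("`indices` must contain `smi` and/or `residual_index`")
  if (is.data.frame(scaled)) {
    comp_cols <- setdiff(names(scaled), "id")
    scaled <- stats::setNames(
      lapply(comp_cols, function(cl) scaled[, c("id", cl)]), comp_cols)
    scaled <- lapply(scaled, function(d) { names(d)[2] <- "scaled"; d })
  }
  groups <- "pooled"
  if (!is.null(sex)) {
    sex <- factor(sex)
    if (length(sex) != nrow(indices))
      stop("`sex` must align with `indices` rows")
    groups <- c(groups, levels(droplevels(sex)))
  }
  rows <- list()
  for (comp in names(scaled)) {
    sc <- scaled[[comp]]
    m <- match(sc$id, indices$id)
    if (anyNA(m))
      stop("id mismatch between scaled ", comp, " and the index table")
    for (ix in idx_cols) {
      for (grp in groups) {
        sel <- if (grp == "pooled") rep(TRUE, nrow(sc)) else
          !is.na(sex[m]) & sex[m] == grp
        rows[[length(rows) + 1L]] <-
          .cor_row("index_component", comp, ix, grp,
                   indices[[ix]][m][sel], sc$scaled[sel], alpha)
      }
    }
  }
  do.call(rbind, rows)
}
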