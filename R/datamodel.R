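#' @keywords internal
"_PACKAGE"

# Field vocabulary shared across the package.  Masses are grams, lengths mm.
.morph_mass_fields <- c("fresh_mass", "dry_mass", "lean_dry_mass",
                        "water_mass", "fat_mass")
.morph_length_fields <- c("pronotum", "tibia", "femur")

#' Construct a validated morphometric dataset
#'
#' Takes a data frame with one row per animal and returns a checked
#' `morph_data` object with derived composition components filled in.
#' Water mass is the difference between fresh and dry mass; fat mass is the
#' difference between dry and lean dry mass.  Rows that violate physical
#' invariants (non-positive mass or length, negative derived water or fat)
#' are retained but flagged rather than dropped, so downstream sample sizes
#' are never changed silently; pass `strict = TRUE` to downstream functions
#' to exclude flagged rows.
#'
#' @param x data frame with at least `id`, `fresh_mass` (g) and one length
#'   column (mm).  Recognised optional columns: `sex`, `diet`, `tibia`,
#'   `femur`, `dry_mass`, `lean_dry_mass`.
#' @param species_label optional text label stored as an attribute.
#' @param provenance optional text describing where the data came from
#'   (file path or generator seed).
#' @return a data frame of class `morph_data` with derived `water_mass` and
#'   `fat_mass` columns where inputs allow, plus logical `flagged` and
#'   character `flag_reason` columns.  The number of flagged rows is
#'   reported with a warning.
#' @export
as_morph_data <- function(x, species_label = NA_character_,
                          provenance = NA_character_) {
  if (!is.data.frame(x)) stop("`x` must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"id" %in% names(x)) stop("column `id` is required")
  if (!"fresh_mass" %in% names(x)) stop("column `fresh_mass` is required")
  if (!any(.morph_length_fields %in% names(x)))
    stop("at least one length column (",
         paste(.morph_length_fields, collapse = ", "), ") is required")

  x$id <- as.character(x$id)
  if (anyDuplicated(x$id))
    stop("ids must be unique; duplicated: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  for (f in c("sex", "diet")) if (f %in% names(x)) x[[f]] <- factor(x[[f]])

  num_fields <- intersect(c(.morph_mass_fields, .morph_length_fields), names(x))
  for (f in num_fields) {
    if (!is.numeric(x[[f]]))
      stop("column `", f, "` must be numeric")
  }

  # derived components (overwrite any stale values)
  if ("dry_mass" %in% names(x))
    x$water_mass <- x$fresh_mass - x$dry_mass
  if (all(c("dry_mass", "lean_dry_mass") %in% names(x)))
    x$fat_mass <- x$dry_mass - x$lean_dry_mass

  flag <- rep("", nrow(x))
  add_flag <- function(flag, bad, reason) {
    bad <- !is.na(bad) & bad
    flag[bad] <- ifelse(nzchar(flag[bad]), paste0(flag[bad], ";", reason), reason)
    flag
  }
  flag <- add_flag(flag, x$fresh_mass <= 0, "nonpositive fresh_mass")
  for (f in intersect(.morph_length_fields, names(x)))
    flag <- add_flag(flag, x[[f]] <= 0, paste0("nonpositive ", f))
  if ("water_mass" %in% names(x))
    flag <- add_flag(flag, x$water_mass < 0, "water_mass negative (dry > fresh)")
  if ("fat_mass" %in% names(x))
    flag <- add_flag(flag, x$fat_mass < 0, "fat_mass negative (lean dry > dry)")

  x$flagged <- nzchar(flag)
  x$flag_reason <- ifelse(x$flagged, flag, NA_character_)
  if (any(x$flagged))
    warning(sum(x$flagged), " of ", nrow(x),
            " records flagged for physically impossible values (retained)")

  attr(x, "species_label") <- species_label
  attr(x, "provenance") <- provenance
  class(x) <- c("morph_data", "data.frame")
  x
}

#' Drop flagged records when strict handling is requested
#' @param data a `morph_data` data frame.
#' @param strict logical; if `TRUE`, flagged rows are removed.
#' @return the (possibly subset) data frame.
#' @export
apply_strict <- function(data, strict = FALSE) {
  if (isTRUE(strict) && "flagged" %in% names(data) && any(data$flagged))
    data <- data[!data$flagged, , drop = FALSE]
  data
}

#' Read a delimited morphometric table
#'
#' Reads a delimited text file (comma by default) with one header row and one
#' row per animal, binds its columns to the standard morphometric fields via
#' `column_map`, converts units, derives composition components and validates
#' the result with [as_morph_data()].
#'
#' @param path path to the delimited file.
#' @param column_map named character vector mapping standard field names to
#'   file column names, e.g. `c(id = "cricket", fresh_mass = "mass_g",
#'   pronotum = "pl_mm")`.  `NULL` means the file already uses standard names.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param units optional named character vector giving the unit of a mass
#'   column (`"g"` or `"mg"`) or a length column (`"mm"` or `"cm"`), named by
#'   standard field.  Everything is stored internally in grams and mm.
#' @param species_label optional text label.
#' @return a `morph_data` data frame.
#' @export
read_morph_table <- function(path, column_map = NULL, sep = ",",
                             units = NULL, species_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols))
      stop("mapped columns absent from file: ",
           paste(missing_cols, collapse = ", "))
    out <- raw[, unname(column_map), drop = FALSE]
    names(out) <- names(column_map)
  } else {
    out <- raw
  }
  num_fields <- intersect(c(.morph_mass_fields, .morph_length_fields), names(out))
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(is.na(v) & !is.na(out[[f]]) & nzchar(trimws(out[[f]])))
    if (length(bad))
      stop("non-numeric value in column `", f, "`, row ", bad[1],
           " (\"", out[[f]][bad[1]], "\")")
    out[[f]] <- v
  }
  if (!is.null(units)) {
    for (f in names(units)) {
      if (!f %in% names(out)) next
      u <- units[[f]]
      if (f %in% .morph_mass_fields) {
        if (u == "mg") out[[f]] <- out[[f]] / 1000
        else if (u != "g") stop("unknown mass unit `", u, "` for ", f)
      } else if (f %in% .morph_length_fields) {
        if (u == "cm") out[[f]] <- out[[f]] * 10
        else if (u != "mm") stop("unknown length unit `", u, "` for ", f)
      }
    }
  }
  as_morph_data(out, species_label = species_label, provenance = path)
}

#' Write a morphometric table
#'
#' Writes the numeric fields with 17 significant digits so that a read/write
#' round trip reproduces every value exactly.
#'
#' @param data a `morph_data` (or plain) data frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_morph_table <- function(data, path, sep = ",") {
  out <- as.data.frame(data)
  out$flagged <- NULL
  out$flag_reason <- NULL
  for (f in names(out)) {
    if (is.numeric(out[[f]])) out[[f]] <- sprintf("%.17g", out[[f]])
    else out[[f]] <- as.character(out[[f]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a declarative dataset configuration
#'
#' A YAML file naming the input table, the column map, units, the separator
#' and optional factor levels, e.g.
#' ```yaml
#' input: crickets.csv
#' sep: ","
#' species_label: "Gryllus texensis"
#' column_map: {id: cricket, fresh_mass: mass, pronotum: pl}
#' units: {fresh_mass: mg}
#' ```
#'
#' @param path path to the YAML config.
#' @return the configuration as a list (class `morph_config`).
#' @export
read_morph_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input)) stop("config must name an `input` table")
  structure(cfg, class = "morph_config")
}

#' Load a morphometric dataset described by a config file
#'
#' @param config_path path to a YAML config (see [read_morph_config()]).
#'   Relative `input` paths are resolved against the config's directory.
#' @return a `morph_data` data frame.
#' @export
morph_from_config <- function(config_path) {
  cfg <- read_morph_config(config_path)
  input <- cfg$input
  if (!file.exists(input))
    input <- file.path(dirname(config_path), input)
  read_morph_table(input,
                   column_map = if (!is.null(cfg$column_map)) unlist(cfg$column_map),
                   sep = if (!is.null(cfg$sep)) cfg$sep else ",",
                   units = if (!is.null(cfg$units)) unlist(cfg$units),
                   species_label = if (!is.null(cfg$species_label)) cfg$species_label
                                   else NA_character_)
}

#' Relative (percentage) size of a body component
#'
#' The component mass divided by a size measure, times 100.  The size measure
#' is usually the fresh body mass, in which case the result is the percentage
#' of body mass made up by the component, but any positive size measure
#' (including a length) is accepted.
#'
#' @param component_mass component mass (g); vectorised.
#' @param size_measure positive size measure (g or mm); vectorised.
#' @return `100 * component_mass / size_measure`.
#' @export
relative_component <- function(component_mass, size_measure) {
  if (any(!is.na(size_measure) & size_measure <= 0))
    stop("size_measure must be positive")
  100 * component_mass / size_measure
}
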