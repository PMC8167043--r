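# Reading/writing deconvoluted LC-MS1 feature tables and the preprocessing
# mass-floor filter. A feature table is a data.frame with columns
# feature_id, neutral_mass (Da), rt (seconds), intensity.

#' Construct a feature table
#'
#' @param neutral_mass Numeric vector of neutral monoisotopic masses (Da).
#' @param rt Numeric vector of retention times in seconds.
#' @param intensity Numeric vector of non-negative intensities.
#' @param feature_id Optional integer ids (default sequential).
#' @return A \code{feature_table}: a data.frame with columns
#'   \code{feature_id}, \code{neutral_mass}, \code{rt}, \code{intensity}.
#' @export
feature_table <- function(neutral_mass, rt, intensity,
                          feature_id = seq_along(neutral_mass)) {
  stopifnot(length(rt) == length(neutral_mass),
            length(intensity) == length(neutral_mass))
  if (anyDuplicated(feature_id)) stop("feature_id values must be unique")
  if (any(neutral_mass <= 0)) stop("neutral_mass must be positive")
  if (any(rt < 0)) stop("rt must be non-negative")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  out <- data.frame(feature_id = as.integer(feature_id),
                    neutral_mass = as.numeric(neutral_mass),
                    rt = as.numeric(rt),
                    intensity = as.numeric(intensity))
  class(out) <- c("feature_table", "data.frame")
  out
}

# Default header names of the Progenesis QI CSV export dialect.
default_column_map <- function() {
  c(rt = "Retention time (min)", neutral_mass = "Neutral mass",
    intensity = "Raw abundance")
}

#' Read a deconvoluted feature table from CSV
#'
#' Reads one row per deconvoluted LC-MS feature. Column names default to the
#' Progenesis QI export dialect; retention times are converted to seconds.
#' Rows with missing or non-numeric required fields are dropped with a
#' warning giving the count.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping \code{rt},
#'   \code{neutral_mass}, \code{intensity} to CSV headers. Case-insensitive
#'   fallbacks \code{rt}/\code{neutral_mass}/\code{intensity} are also
#'   accepted.
#' @param rt_unit Unit of the retention-time column in the file:
#'   \code{"minutes"} (Progenesis default) or \code{"seconds"}.
#' @param sep Field delimiter.
#' @return A [feature_table()] with attributes \code{rt_unit_of_source},
#'   \code{source_path} and \code{n_dropped}.
#' @export
read_features <- function(path, column_map = default_column_map(),
                          rt_unit = c("minutes", "seconds"), sep = ",") {
  rt_unit <- match.arg(rt_unit)
  df <- utils::read.csv(path, check.names = FALSE, sep = sep,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty feature file: ", path)
  resolve <- function(key) {
    cand <- c(column_map[[key]], key)
    hit <- which(tolower(names(df)) %in% tolower(cand))
    if (!length(hit)) {
      stop(sprintf("cannot resolve '%s' column; available headers: %s",
                   key, paste(names(df), collapse = ", ")))
    }
    hit[1L]
  }
  rt <- suppressWarnings(as.numeric(df[[resolve("rt")]]))
  mass <- suppressWarnings(as.numeric(df[[resolve("neutral_mass")]]))
  inten <- suppressWarnings(as.numeric(df[[resolve("intensity")]]))
  keep <- is.finite(rt) & is.finite(mass) & is.finite(inten)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(sprintf("dropped %d row(s) with missing/non-numeric fields", n_drop))
  }
  if (!any(keep)) stop("no parseable feature rows in ", path)
  if (rt_unit == "minutes") rt <- rt * 60
  out <- feature_table(neutral_mass = mass[keep], rt = rt[keep],
                       intensity = inten[keep])
  attr(out, "rt_unit_of_source") <- rt_unit
  attr(out, "source_path") <- path
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write a feature table to CSV
#'
#' Writes the same dialect [read_features()] reads (retention time in
#' minutes under the Progenesis header names).
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(table, path) {
  out <- data.frame(`Retention time (min)` = table$rt / 60,
                    `Neutral mass` = table$neutral_mass,
                    `Raw abundance` = table$intensity,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default mass floor for a peptide set
#'
#' The smallest conceivable glycopeptide mass: the minimum peptide backbone
#' mass plus one HexNAc residue (1359.594 Da for the IgG Fc peptides
#' EEQYNSTYR/EEQFNSTFR).
#'
#' @inheritParams build_candidate_db
#' @return The floor mass (Da).
#' @export
default_mass_floor <- function(peptides, fixed_mods = default_fixed_mods()) {
  min(peptide_mass(peptides, fixed_mods)) + unname(GLYCAN_RESIDUES["hexnac"])
}

#' Remove features below a mass floor
#'
#' Retains features with \code{neutral_mass >= floor_mass} (the boundary is
#' inclusive: only masses strictly lower than the floor are removed).
#' Row order is preserved; the removed count is recorded in the
#' \code{n_floored} attribute.
#'
#' @param table A [feature_table()].
#' @param floor_mass Mass floor in Da.
#' @return The filtered [feature_table()].
#' @export
mass_floor_filter <- function(table, floor_mass) {
  stopifnot(floor_mass >= 0)
  keep <- table$neutral_mass >= floor_mass
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rt_unit_of_source") <- attr(table, "rt_unit_of_source")
  attr(out, "source_path") <- attr(table, "source_path")
  attr(out, "n_floored") <- sum(!keep)
  class(out) <- c("feature_table", "data.frame")
  out
}
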