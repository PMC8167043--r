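# Main entry point: fit the glycopeptide network model to a feature table
# and return a classed object with the usual methods.

#' Glycopeptide network assignment and quantitation
#'
#' Runs the full analysis over a deconvoluted LC-MS1 feature table:
#' mass-floor filtering, monosaccharide mass-difference edge detection
#' under retention-time windows, connected-component clustering,
#' reference-node matching against the peptide x glycan candidate
#' database, composition propagation, split-peak merging, per-peptide
#' relative abundance and glycosylation attribute roll-ups.
#'
#' @param features A [feature_table()] (e.g. from [read_features()]).
#' @param peptides Character vector of candidate glycopeptide backbone
#'   sequences.
#' @param glycans Glycan composition library data.frame
#'   ([default_glycan_library()] by default, or [read_glycan_library()]).
#' @param fixed_mods Fixed modifications for peptide masses.
#' @param floor_mass Mass floor in Da; \code{NULL} (default) uses
#'   [default_mass_floor()] (smallest peptide + HexNAc).
#' @param residue_set Residue edge set ([default_residue_set()]).
#' @param mass_tol Edge mass tolerance in Da.
#' @param match_tol Reference-match tolerance in Da.
#' @param verify_tol Propagation mass-verification tolerance in Da.
#' @param mode Assignment mode: \code{"auto"}, \code{"from-file"} or
#'   \code{"interactive"} (see [assign_all()]).
#' @param decisions Decisions data.frame for \code{mode = "from-file"}.
#' @param scope Quantitation scope, \code{"peptide"} or \code{"all"}.
#' @param rules Attribute rules ([default_attribute_rules()]).
#' @return An object of class \code{glyconet}: a list with the filtered
#'   \code{features}, \code{edges}, \code{clusters}, assignment
#'   \code{result}, \code{merged} quantitation rows, \code{profile},
#'   \code{attributes}, stage \code{counts} and the \code{control}
#'   parameters.
#' @seealso [summary.glyconet()], [plot.glyconet()], [run_pipeline()]
#' @examples
#' sim <- generate_features(fig_fixture_serum_igg(seed = 1))
#' fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
#' fit
#' @export
glyconet <- function(features, peptides, glycans = default_glycan_library(),
                     fixed_mods = default_fixed_mods(), floor_mass = NULL,
                     residue_set = default_residue_set(), mass_tol = 0.02,
                     match_tol = 0.02, verify_tol = 0.03,
                     mode = c("auto", "from-file", "interactive"),
                     decisions = NULL, scope = c("peptide", "all"),
                     rules = default_attribute_rules()) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  n_in <- nrow(features)
  if (is.null(floor_mass)) floor_mass <- default_mass_floor(peptides, fixed_mods)
  feat <- mass_floor_filter(features, floor_mass)
  db <- build_candidate_db(peptides, glycans, fixed_mods)
  if (nrow(feat) == 0L) {
    edges <- detect_edges(feature_table(1, 0, 0), residue_set, mass_tol)[0, ]
    clusters <- list(networks = list(), singletons = integer(0))
    result <- assign_all(feat, clusters, db, mode = "auto")
  } else {
    edges <- detect_edges(feat, residue_set, mass_tol)
    clusters <- cluster_subgraphs(feat, edges)
    result <- assign_all(feat, clusters, db, mode = mode, decisions = decisions,
                         match_tol = match_tol, verify_tol = verify_tol,
                         residue_set = residue_set)
  }
  merged <- merge_split_peaks(result$assignments)
  profile <- if (nrow(merged) > 0L) relative_abundance(merged, scope) else NULL
  attributes <- if (!is.null(profile)) attribute_rollup(profile, rules) else NULL
  asg <- result$assignments
  assigned_net <- unique(asg$network_id)
  n_network_nodes <- sum(vapply(clusters$networks,
                                function(nw) length(nw$node_ids), integer(1L)))
  # network nodes not in the assignment table: members of unmatched/rejected
  # networks plus nodes unreachable from an accepted reference
  n_unassigned_nodes <- n_network_nodes - nrow(asg)
  counts <- c(
    features_in = n_in,
    floored = attr(feat, "n_floored"),
    retained = nrow(feat),
    edges = nrow(edges),
    networks = length(clusters$networks),
    networks_assigned = length(assigned_net),
    singletons = length(clusters$singletons),
    nodes_assigned = sum(asg$status == "assigned"),
    nodes_ambiguous = sum(asg$status == "ambiguous"),
    nodes_mass_inconsistent = sum(asg$status == "mass_inconsistent"),
    nodes_unassigned = n_unassigned_nodes
  )
  structure(list(
    features = feat, edges = edges, clusters = clusters, result = result,
    merged = merged, profile = profile, attributes = attributes,
    counts = counts, candidate_db = db, peptides = peptides,
    control = list(floor_mass = floor_mass, mass_tol = mass_tol,
                   match_tol = match_tol, verify_tol = verify_tol,
                   mode = mode, scope = scope, fixed_mods = fixed_mods,
                   residue_set = residue_set),
    call = match.call()
  ), class = "glyconet")
}

#' @export
print.glyconet <- function(x, ...) {
  cat("Glycopeptide network assignment\n")
  cat(sprintf("  features: %d in, %d below %.3f Da floor, %d retained\n",
              x$counts[["features_in"]], x$counts[["floored"]],
              x$control$floor_mass, x$counts[["retained"]]))
  cat(sprintf("  networks: %d (%d assigned), %d singleton features\n",
              x$counts[["networks"]], x$counts[["networks_assigned"]],
              x$counts[["singletons"]]))
  cat(sprintf("  nodes: %d assigned, %d ambiguous, %d mass-inconsistent\n",
              x$counts[["nodes_assigned"]], x$counts[["nodes_ambiguous"]],
              x$counts[["nodes_mass_inconsistent"]]))
  if (!is.null(x$profile)) {
    for (p in unique(x$profile$peptide)) {
      n <- sum(x$profile$peptide == p)
      top <- x$profile[x$profile$peptide == p, ]
      top <- top[which.max(top$relative_abundance), ]
      cat(sprintf("  %s: %d glycoforms, top %s (%.1f%%)\n", p, n,
                  top$composition, top$relative_abundance))
    }
  }
  invisible(x)
}

#' Summarise a glyconet fit
#'
#' @param object A \code{glyconet} object.
#' @param threshold Minimum relative abundance (percent) for a glycoform to
#'   be listed in the printed table (all rows are kept in the returned
#'   object; the threshold affects display only).
#' @param ... Unused.
#' @return A \code{summary.glyconet} list with \code{counts},
#'   \code{profile}, \code{attributes} and \code{threshold}.
#' @export
summary.glyconet <- function(object, threshold = 0, ...) {
  structure(list(counts = object$counts, profile = object$profile,
                 attributes = object$attributes, threshold = threshold),
            class = "summary.glyconet")
}

#' @export
print.summary.glyconet <- function(x, ...) {
  cat("Stage counts:\n")
  print(x$counts)
  if (!is.null(x$profile)) {
    pr <- x$profile[x$profile$relative_abundance >= x$threshold, , drop = FALSE]
    cat("\nGlycoform relative abundance (%):\n")
    print(data.frame(peptide = pr$peptide, composition = pr$composition,
                     percent = round(pr$relative_abundance, 3)),
          row.names = FALSE)
    cat("\nAttribute summary (%):\n")
    at <- x$attributes
    print(data.frame(peptide = at$peptide, attribute = at$attribute,
                     percent = round(at$relative_abundance, 3)),
          row.names = FALSE)
  } else {
    cat("\nNo assigned glycoforms.\n")
  }
  invisible(x)
}

#' Residual mass errors of assigned nodes
#'
#' @param object A \code{glyconet} object.
#' @param ... Unused.
#' @return Numeric vector of observed-minus-expected mass errors (Da) for
#'   \code{status = "assigned"} nodes, named by feature id.
#' @export
residuals.glyconet <- function(object, ...) {
  a <- object$result$assignments
  a <- a[a$status == "assigned", , drop = FALSE]
  stats::setNames(a$mass_error_da, a$feature_id)
}

# Table behind the bubble chart: one row per retained feature.
bubble_table <- function(fit) {
  feat <- fit$features
  asg <- fit$result$assignments
  i <- match(feat$feature_id, asg$feature_id)
  data.frame(feature_id = feat$feature_id,
             rt_min = feat$rt / 60,
             neutral_mass = feat$neutral_mass,
             intensity = feat$intensity,
             bubble_size = if (nrow(feat)) sqrt(feat$intensity / max(feat$intensity))
                           else numeric(0),
             peptide = ifelse(is.na(i), NA_character_, asg$peptide[i]),
             composition = ifelse(is.na(i), NA_character_, asg$composition[i]),
             network_id = ifelse(is.na(i), NA_integer_, asg$network_id[i]),
             group = ifelse(is.na(i), "unassigned", asg$peptide[i]),
             stringsAsFactors = FALSE)
}

#' Bubble chart of a glyconet fit
#'
#' Retention time (minutes) against neutral mass, bubble area proportional
#' to intensity, assigned networks coloured by peptide and unassigned
#' features grey.
#'
#' @param x A \code{glyconet} object.
#' @param label Label assigned bubbles with their composition.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glyconet <- function(x, label = FALSE, ...) {
  tb <- bubble_table(x)
  groups <- setdiff(unique(tb$group), "unassigned")
  pal <- grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")
  col <- rep("grey70", nrow(tb))
  for (gi in seq_along(groups)) col[tb$group == groups[gi]] <- pal[gi]
  graphics::plot(tb$rt_min, tb$neutral_mass,
                 cex = 0.5 + 2.5 * tb$bubble_size,
                 col = grDevices::adjustcolor(col, alpha.f = 0.7), pch = 16,
                 xlab = "Retention time (min)", ylab = "Neutral mass (Da)",
                 ...)
  if (label) {
    sel <- !is.na(tb$composition)
    graphics::text(tb$rt_min[sel], tb$neutral_mass[sel], tb$composition[sel],
                   pos = 4, cex = 0.6)
  }
  if (length(groups)) {
    graphics::legend("topleft", legend = c(groups, "unassigned"),
                     col = c(pal[seq_along(groups)], "grey70"), pch = 16,
                     bty = "n", cex = 0.8)
  }
  invisible(tb)
}

#' Export the bubble chart and its underlying table
#'
#' Writes a PNG of [plot.glyconet()] and always writes the plotted table as
#' CSV next to it, so the figure is reproducible from text.
#'
#' @param fit A \code{glyconet} object.
#' @param path Output PNG path; the CSV twin replaces the extension with
#'   \code{.csv}.
#' @return Invisibly, a list with \code{png} and \code{csv} paths.
#' @export
bubble_chart_export <- function(fit, path) {
  csv <- sub("\\.[A-Za-z]+$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  utils::write.csv(bubble_table(fit), csv, row.names = FALSE)
  grDevices::png(path, width = 1200, height = 800, res = 140)
  on.exit(grDevices::dev.off())
  plot(fit)
  invisible(list(png = path, csv = csv))
}
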