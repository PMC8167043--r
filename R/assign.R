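# Reference-node matching against the glycopeptide candidate database and
# composition propagation along residue edges.

#' Match a network's reference node against the candidate database
#'
#' Returns every candidate whose mass lies within \code{match_tol} of the
#' reference node's neutral mass, ranked by absolute mass error; ties are
#' broken in favour of the smaller composition (fewer residues). An empty
#' result means the network is unassigned and excluded downstream.
#'
#' @param network One network from [cluster_subgraphs()].
#' @param candidate_db Data.frame from [build_candidate_db()].
#' @param match_tol Absolute tolerance in Da (default 0.02).
#' @return A data.frame with columns \code{network_id}, \code{peptide},
#'   \code{composition}, \code{candidate_mass}, \code{mass_error_da},
#'   \code{mass_error_ppm}, ranked best first.
#' @export
match_reference <- function(network, candidate_db, match_tol = 0.02) {
  err <- candidate_db$mono_mass - network$reference_mass
  hit <- which(abs(err) <= match_tol)
  if (!length(hit)) {
    return(data.frame(network_id = integer(0), peptide = character(0),
                      composition = character(0), candidate_mass = numeric(0),
                      mass_error_da = numeric(0), mass_error_ppm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  size <- rowSums(parse_composition(candidate_db$composition[hit]))
  ord <- order(abs(err[hit]), size, candidate_db$peptide[hit],
               candidate_db$composition[hit])
  hit <- hit[ord]
  data.frame(network_id = network$network_id,
             peptide = candidate_db$peptide[hit],
             composition = candidate_db$composition[hit],
             candidate_mass = candidate_db$mono_mass[hit],
             mass_error_da = err[hit],
             mass_error_ppm = err[hit] / network$reference_mass * 1e6,
             stringsAsFactors = FALSE)
}

#' Propagate a reference composition across a network
#'
#' Starting from the reference node's accepted composition, traverses the
#' network's residue edges: crossing an edge toward higher mass adds the
#' edge residue's composition increment, toward lower mass subtracts it.
#' Traversal is relaxed to a fixpoint so the result is independent of visit
#' order: a node reachable with two different compositions is flagged
#' \code{ambiguous}; a path that would drive any residue count negative is
#' pruned. Every uniquely determined composition is verified against the
#' node's observed mass (\code{mass_inconsistent} outside
#' \code{verify_tol}).
#'
#' @param table A [feature_table()] containing the network's nodes.
#' @param network One network from [cluster_subgraphs()].
#' @param accepted_match One row of a [match_reference()] result (the
#'   accepted candidate for this network).
#' @param residue_set Residue set used to build the edges.
#' @param verify_tol Mass-verification tolerance in Da (default 0.03,
#'   allowing accumulated error along paths).
#' @return A data.frame with one row per reached node: \code{feature_id},
#'   \code{peptide}, \code{composition}, \code{status} (\code{assigned},
#'   \code{ambiguous} or \code{mass_inconsistent}), \code{neutral_mass},
#'   \code{rt}, \code{intensity}, \code{network_id}, \code{mass_error_da}.
#' @export
propagate <- function(table, network, accepted_match,
                      residue_set = default_residue_set(),
                      verify_tol = 0.03) {
  if (!(accepted_match$network_id == network$network_id) ||
      !(network$reference_id %in% network$node_ids)) {
    stop("accepted match does not belong to this network")
  }
  ids <- network$node_ids
  edges <- network$edges
  deltas <- as.matrix(residue_set[, unname(COMP_LETTERS), drop = FALSE])
  rownames(deltas) <- residue_set$name
  # candidate composition sets per node, keyed by canonical short form
  comps <- stats::setNames(vector("list", length(ids)), as.character(ids))
  ref_comp <- parse_composition(accepted_match$composition)[1L, ]
  comps[[as.character(network$reference_id)]] <- list(ref_comp)
  add_comp <- function(set, cand) {
    for (x in set) if (all(x == cand)) return(set)
    c(set, list(cand))
  }
  backbone_mass <- accepted_match$candidate_mass - composition_mass(accepted_match$composition)
  n_nodes <- length(ids)
  for (iter in seq_len(n_nodes)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      lo <- as.character(edges$lo_id[e]); hi <- as.character(edges$hi_id[e])
      d <- deltas[edges$residue[e], ]
      for (x in comps[[lo]]) {  # upward: add residue
        before <- length(comps[[hi]])
        comps[[hi]] <- add_comp(comps[[hi]], x + d)
        if (length(comps[[hi]]) != before) changed <- TRUE
      }
      for (x in comps[[hi]]) {  # downward: subtract, prune negatives
        cand <- x - d
        if (any(cand < 0L)) next
        before <- length(comps[[lo]])
        comps[[lo]] <- add_comp(comps[[lo]], cand)
        if (length(comps[[lo]]) != before) changed <- TRUE
      }
    }
    if (!changed) break
  }
  rows <- lapply(ids, function(fid) {
    set <- comps[[as.character(fid)]]
    if (length(set) == 0L) return(NULL)  # unreachable (all paths pruned)
    feat <- table[match(fid, table$feature_id), ]
    if (length(set) > 1L) {
      return(data.frame(feature_id = fid, peptide = accepted_match$peptide,
                        composition = NA_character_, status = "ambiguous",
                        neutral_mass = feat$neutral_mass, rt = feat$rt,
                        intensity = feat$intensity,
                        network_id = network$network_id,
                        mass_error_da = NA_real_, stringsAsFactors = FALSE))
    }
    comp <- set[[1L]]
    expected <- backbone_mass + composition_mass(comp)
    err <- feat$neutral_mass - expected
    data.frame(feature_id = fid, peptide = accepted_match$peptide,
               composition = format_composition(comp),
               status = if (abs(err) <= verify_tol) "assigned" else "mass_inconsistent",
               neutral_mass = feat$neutral_mass, rt = feat$rt,
               intensity = feat$intensity, network_id = network$network_id,
               mass_error_da = err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve reference matches and propagate across all networks
#'
#' Orchestrates [match_reference()] and [propagate()] for every network.
#' Modes: \code{"auto"} accepts the best-ranked candidate per network
#' (warning when several candidates fall within tolerance);
#' \code{"from-file"} takes a decisions data.frame with columns
#' \code{network_id} and \code{accept} (a \code{"peptide|composition"}
#' candidate key, or \code{"reject"}); \code{"interactive"} prompts for
#' each network on the console and requires an interactive session.
#'
#' @param table A [feature_table()].
#' @param clusters Result of [cluster_subgraphs()].
#' @param candidate_db Data.frame from [build_candidate_db()].
#' @param mode One of \code{"auto"}, \code{"from-file"},
#'   \code{"interactive"}.
#' @param decisions Decisions data.frame (required for
#'   \code{mode = "from-file"}); networks with a within-tolerance match
#'   must each have a row.
#' @param match_tol,verify_tol,residue_set Passed through to
#'   [match_reference()] and [propagate()].
#' @return A list: \code{assignments} (row-bound [propagate()] output over
#'   accepted networks), \code{matches} (all candidate matches, all
#'   networks), \code{accepted} (one row per accepted network),
#'   \code{unassigned_networks} (ids with no or rejected match),
#'   \code{singletons}.
#' @export
assign_all <- function(table, clusters, candidate_db,
                       mode = c("auto", "from-file", "interactive"),
                       decisions = NULL, match_tol = 0.02, verify_tol = 0.03,
                       residue_set = default_residue_set()) {
  mode <- match.arg(mode)
  matches <- lapply(clusters$networks, match_reference, candidate_db = candidate_db,
                    match_tol = match_tol)
  all_matches <- do.call(rbind, c(matches, list(match_reference(
    list(network_id = integer(0), reference_mass = numeric(0)),
    candidate_db[0, ], match_tol))))
  accepted <- list()
  unassigned <- integer(0)
  for (k in seq_along(clusters$networks)) {
    nw <- clusters$networks[[k]]
    m <- matches[[k]]
    if (nrow(m) == 0L) { unassigned <- c(unassigned, nw$network_id); next }
    if (mode == "auto") {
      if (nrow(m) > 1L) {
        warning(sprintf(
          "network %d: %d candidates within tolerance; accepting best (%s + %s)",
          nw$network_id, nrow(m), m$peptide[1L], m$composition[1L]))
      }
      accepted[[length(accepted) + 1L]] <- m[1L, , drop = FALSE]
    } else if (mode == "from-file") {
      if (is.null(decisions)) stop("mode 'from-file' requires a decisions table")
      row <- decisions[decisions$network_id == nw$network_id, , drop = FALSE]
      if (nrow(row) == 0L) {
        stop(sprintf("no decision for network(s): %s",
                     paste(setdiff(vapply(clusters$networks, `[[`, integer(1L),
                                          "network_id")[vapply(matches, nrow, integer(1L)) > 0],
                                   decisions$network_id), collapse = ", ")))
      }
      key <- as.character(row$accept[1L])
      if (identical(tolower(key), "reject")) {
        unassigned <- c(unassigned, nw$network_id); next
      }
      sel <- which(paste(m$peptide, m$composition, sep = "|") == key)
      if (!length(sel)) {
        stop(sprintf("network %d: decision '%s' is not a within-tolerance candidate",
                     nw$network_id, key))
      }
      accepted[[length(accepted) + 1L]] <- m[sel[1L], , drop = FALSE]
    } else {  # interactive
      if (!interactive()) {
        stop("mode 'interactive' needs an interactive session; use 'auto' or 'from-file'")
      }
      cat(sprintf("Network %d (reference mass %.4f Da, %d nodes):\n",
                  nw$network_id, nw$reference_mass, length(nw$node_ids)))
      for (j in seq_len(nrow(m))) {
        cat(sprintf("  [%d] %s + %s (%.4f Da, %+.4f Da)\n", j, m$peptide[j],
                    m$composition[j], m$candidate_mass[j], m$mass_error_da[j]))
      }
      ans <- readline("accept candidate number (empty = reject): ")
      j <- suppressWarnings(as.integer(ans))
      if (is.na(j) || j < 1L || j > nrow(m)) {
        unassigned <- c(unassigned, nw$network_id)
      } else {
        accepted[[length(accepted) + 1L]] <- m[j, , drop = FALSE]
      }
    }
  }
  accepted_df <- if (length(accepted)) do.call(rbind, accepted) else all_matches[0, ]
  assignments <- NULL
  for (i in seq_len(nrow(accepted_df))) {
    nw <- clusters$networks[[match(accepted_df$network_id[i],
                                   vapply(clusters$networks, `[[`, integer(1L),
                                          "network_id"))]]
    assignments <- rbind(assignments,
                         propagate(table, nw, accepted_df[i, , drop = FALSE],
                                   residue_set = residue_set,
                                   verify_tol = verify_tol))
  }
  if (is.null(assignments)) {
    assignments <- data.frame(feature_id = integer(0), peptide = character(0),
                              composition = character(0), status = character(0),
                              neutral_mass = numeric(0), rt = numeric(0),
                              intensity = numeric(0), network_id = integer(0),
                              mass_error_da = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(assignments) <- NULL
  list(assignments = assignments, matches = all_matches,
       accepted = accepted_df, unassigned_networks = sort(unassigned),
       singletons = clusters$singletons)
}
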