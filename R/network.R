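# Glycopeptide graph construction: residue mass-difference edges under
# per-residue retention-time windows, then connected-component subgraphs.

#' Default monosaccharide residue edge set
#'
#' Mass differences searched between feature pairs, each with its
#' retention-time window: 30 s for Hex, HexNAc and Fuc; 50 s for the
#' composite HexHexNAc step (one Hex plus one HexNAc, bridging a missing
#' intermediate glycoform); 500 s for NeuAc, whose addition shifts
#' retention strongly. NeuGc is available but off by default.
#'
#' @param rt_windows Optional named numeric vector overriding windows
#'   (seconds) per residue name.
#' @param include_neugc Include the NeuGc (307.090 Da) edge.
#' @return A data.frame with columns \code{name}, \code{delta_mass} (Da),
#'   \code{rt_window} (s) and composition increment columns
#'   \code{hexnac, hex, fuc, neuac, neugc}.
#' @export
default_residue_set <- function(rt_windows = NULL, include_neugc = FALSE) {
  rs <- data.frame(
    name = c("HexNAc", "Hex", "Fuc", "NeuAc", "HexHexNAc", "NeuGc"),
    delta_mass = c(GLYCAN_RESIDUES[["hexnac"]], GLYCAN_RESIDUES[["hex"]],
                   GLYCAN_RESIDUES[["fuc"]], GLYCAN_RESIDUES[["neuac"]],
                   GLYCAN_RESIDUES[["hexnac"]] + GLYCAN_RESIDUES[["hex"]],
                   GLYCAN_RESIDUES[["neugc"]]),
    rt_window = c(30, 30, 30, 500, 50, 500),
    hexnac = c(1L, 0L, 0L, 0L, 1L, 0L),
    hex    = c(0L, 1L, 0L, 0L, 1L, 0L),
    fuc    = c(0L, 0L, 1L, 0L, 0L, 0L),
    neuac  = c(0L, 0L, 0L, 1L, 0L, 0L),
    neugc  = c(0L, 0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  if (!include_neugc) rs <- rs[rs$name != "NeuGc", , drop = FALSE]
  if (!is.null(rt_windows)) {
    hit <- intersect(names(rt_windows), rs$name)
    rs$rt_window[match(hit, rs$name)] <- rt_windows[hit]
  }
  rownames(rs) <- NULL
  rs
}

#' Detect monosaccharide mass-difference edges
#'
#' Finds every feature pair whose neutral-mass difference matches a residue
#' delta within \code{mass_tol} and whose retention-time gap is within that
#' residue's window. A pair matching several residues keeps only the
#' minimum-|ppm error| match. Uses a mass-sorted sweep per residue; output
#' is ordered by (lo_id, hi_id) and independent of input row order.
#'
#' @param table A [feature_table()].
#' @param residue_set A residue data.frame from [default_residue_set()].
#' @param mass_tol Absolute mass tolerance in Da (default 0.02), or set
#'   \code{ppm_mode = TRUE} to interpret it as ppm of the pair mean mass.
#' @param ppm_mode Interpret \code{mass_tol} in ppm.
#' @return A data.frame with columns \code{lo_id}, \code{hi_id},
#'   \code{residue}, \code{delta_observed}, \code{ppm_error}, \code{rt_gap}.
#' @export
detect_edges <- function(table, residue_set = default_residue_set(),
                         mass_tol = 0.02, ppm_mode = FALSE) {
  stopifnot(nrow(table) >= 1L, mass_tol > 0)
  ord <- order(table$neutral_mass, table$feature_id)
  mass <- table$neutral_mass[ord]
  rt <- table$rt[ord]
  id <- table$feature_id[ord]
  n <- length(mass)
  acc <- vector("list", nrow(residue_set))
  for (r in seq_len(nrow(residue_set))) {
    delta <- residue_set$delta_mass[r]
    win <- residue_set$rt_window[r]
    tol <- if (ppm_mode) mass_tol * 1e-6 * (mass + delta / 2) else rep(mass_tol, n)
    lo_idx <- integer(0); hi_idx <- integer(0)
    j1 <- 1L; j2 <- 1L
    for (i in seq_len(n)) {
      target <- mass[i] + delta
      while (j1 <= n && mass[j1] < target - tol[i]) j1 <- j1 + 1L
      if (j2 < j1) j2 <- j1
      while (j2 <= n && mass[j2] <= target + tol[i]) j2 <- j2 + 1L
      if (j1 < j2) {
        js <- j1:(j2 - 1L)
        js <- js[abs(rt[js] - rt[i]) <= win & js != i]
        if (length(js)) {
          lo_idx <- c(lo_idx, rep.int(i, length(js)))
          hi_idx <- c(hi_idx, js)
        }
      }
    }
    if (length(lo_idx)) {
      dobs <- mass[hi_idx] - mass[lo_idx]
      acc[[r]] <- data.frame(
        lo_id = id[lo_idx], hi_id = id[hi_idx],
        residue = residue_set$name[r],
        delta_observed = dobs,
        ppm_error = (dobs - delta) / delta * 1e6,
        rt_gap = abs(rt[hi_idx] - rt[lo_idx]),
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- do.call(rbind, acc[!vapply(acc, is.null, logical(1L))])
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(lo_id = integer(0), hi_id = integer(0),
                      residue = character(0), delta_observed = numeric(0),
                      ppm_error = numeric(0), rt_gap = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # one edge per pair: keep the residue with the smallest |ppm error|
  key <- paste(edges$lo_id, edges$hi_id, sep = "_")
  edges <- edges[order(key, abs(edges$ppm_error)), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$lo_id, edges$hi_id, sep = "_")), ,
                 drop = FALSE]
  edges <- edges[order(edges$lo_id, edges$hi_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Cluster features into glycopeptide networks
#'
#' Connected components of the undirected edge graph. Features with no
#' incident edge are reported separately as singletons, not as networks.
#' Each network's reference node is its lowest-neutral-mass feature;
#' networks are sorted and numbered by reference mass.
#'
#' @param table A [feature_table()].
#' @param edges Edge data.frame from [detect_edges()].
#' @return A list with elements \code{networks} (list of lists with
#'   \code{network_id}, \code{node_ids}, \code{edges},
#'   \code{reference_id}, \code{reference_mass}) and \code{singletons}
#'   (feature ids).
#' @export
cluster_subgraphs <- function(table, edges) {
  in_edge <- unique(c(edges$lo_id, edges$hi_id))
  if (!all(in_edge %in% table$feature_id)) {
    stop("edges reference feature ids not present in the table")
  }
  singletons <- setdiff(table$feature_id, in_edge)
  if (nrow(edges) == 0L) {
    return(list(networks = list(), singletons = sort(singletons)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("lo_id", "hi_id")], directed = FALSE,
    vertices = data.frame(name = as.character(in_edge))
  )
  comp <- igraph::components(g)
  member <- split(as.integer(names(comp$membership)), comp$membership)
  mass_of <- table$neutral_mass[match(unlist(lapply(member, min)), table$feature_id)]
  networks <- lapply(member, function(ids) {
    masses <- table$neutral_mass[match(ids, table$feature_id)]
    ref <- ids[which.min(masses)]
    sub <- edges[edges$lo_id %in% ids & edges$hi_id %in% ids, , drop = FALSE]
    rownames(sub) <- NULL
    list(node_ids = sort(ids), edges = sub, reference_id = ref,
         reference_mass = min(masses))
  })
  refs <- vapply(networks, `[[`, numeric(1L), "reference_mass")
  networks <- networks[order(refs)]
  for (k in seq_along(networks)) networks[[k]]$network_id <- k
  list(networks = networks, singletons = sort(singletons))
}

#' Export edge and node tables for external graph viewers
#'
#' Writes the edge list and a node table (GraphML-compatible columns) as
#' CSV.
#'
#' @param table A [feature_table()].
#' @param edges Edge data.frame from [detect_edges()].
#' @param clusters Result of [cluster_subgraphs()].
#' @param edge_path,node_path Output CSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
export_network_tables <- function(table, edges, clusters, edge_path, node_path) {
  utils::write.csv(edges, edge_path, row.names = FALSE)
  net_of <- rep(NA_integer_, nrow(table))
  ref <- rep(FALSE, nrow(table))
  for (nw in clusters$networks) {
    net_of[match(nw$node_ids, table$feature_id)] <- nw$network_id
    ref[match(nw$reference_id, table$feature_id)] <- TRUE
  }
  nodes <- data.frame(id = table$feature_id, neutral_mass = table$neutral_mass,
                      rt = table$rt, intensity = table$intensity,
                      network_id = net_of, is_reference = ref)
  utils::write.csv(nodes, node_path, row.names = FALSE)
  invisible(list(edges = edge_path, nodes = node_path))
}
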