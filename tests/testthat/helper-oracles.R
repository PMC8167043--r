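# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately use naive all-pairs / BFS algorithms so
# they stay independent of the package's sweep and propagation code paths.

# All-pairs edge detection: O(n^2) over ordered mass pairs, min-|ppm|
# residue per pair.
bf_edges <- function(table, residue_set = default_residue_set(),
                     mass_tol = 0.02) {
  n <- nrow(table)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dm <- table$neutral_mass[j] - table$neutral_mass[i]
      if (dm <= 0) next
      drt <- abs(table$rt[j] - table$rt[i])
      best_r <- NA_integer_
      best_ppm <- Inf
      for (r in seq_len(nrow(residue_set))) {
        err <- dm - residue_set$delta_mass[r]
        if (abs(err) <= mass_tol && drt <= residue_set$rt_window[r]) {
          ppm <- abs(err / residue_set$delta_mass[r] * 1e6)
          if (ppm < best_ppm) { best_ppm <- ppm; best_r <- r }
        }
      }
      if (!is.na(best_r)) {
        rows[[length(rows) + 1L]] <- data.frame(
          lo_id = table$feature_id[i], hi_id = table$feature_id[j],
          residue = residue_set$name[best_r], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lo_id = integer(0), hi_id = integer(0),
               residue = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$lo_id, out$hi_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Connected components over an edge list by breadth-first search; returns a
# list of integer id vectors (components with >= 2 nodes only).
bf_components <- function(ids, edges) {
  adj <- lapply(setNames(vector("list", length(ids)), as.character(ids)),
                identity)
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges$lo_id[k]); b <- as.character(edges$hi_id[k])
    adj[[a]] <- c(adj[[a]], edges$hi_id[k])
    adj[[b]] <- c(adj[[b]], edges$lo_id[k])
  }
  seen <- setNames(rep(FALSE, length(ids)), as.character(ids))
  comps <- list()
  for (id in ids) {
    if (seen[[as.character(id)]] || !length(adj[[as.character(id)]])) next
    queue <- id
    members <- integer(0)
    seen[[as.character(id)]] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, v)
      for (w in adj[[as.character(v)]]) {
        if (!seen[[as.character(w)]]) {
          seen[[as.character(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# Brute-force database search: for each component whose lowest-mass node
# matches the candidate db, match every member's mass against the db
# directly (no propagation).
bf_assign <- function(table, db, residue_set = default_residue_set(),
                      mass_tol = 0.02, match_tol = 0.02) {
  edges <- bf_edges(table, residue_set, mass_tol)
  comps <- bf_components(table$feature_id, edges)
  rows <- list()
  for (members in comps) {
    masses <- table$neutral_mass[match(members, table$feature_id)]
    ref_mass <- min(masses)
    err <- abs(db$mono_mass - ref_mass)
    if (min(err) > match_tol) next
    for (k in seq_along(members)) {
      nerr <- abs(db$mono_mass - masses[k])
      hit <- which(nerr <= match_tol)
      if (!length(hit)) next
      best <- hit[order(nerr[hit],
                        rowSums(parse_composition(db$composition[hit])))][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = members[k], peptide = db$peptide[best],
        composition = db$composition[best], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = integer(0), peptide = character(0),
               composition = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A random single-peptide synthetic spec: planted profile sampled from the
# default library, plus decoy ladders and scatter.
random_spec <- function(seed, mass_error_sd = 0, peptide = NULL) {
  set.seed(seed)
  pool <- c("EEQYNSTYR", "EEQFNSTFR", "TPLGDTTHTSGSENK")
  if (is.null(peptide)) peptide <- sample(pool, 1L)
  lib <- default_glycan_library()
  k <- sample(6:14, 1L)
  comps <- sample(lib$composition, k)
  fr <- stats::runif(k, 0.2, 1); fr <- fr / sum(fr)
  synthetic_spec(
    peptides = data.frame(sequence = peptide,
                          base_rt = stats::runif(1L, 500, 1200),
                          stringsAsFactors = FALSE),
    profiles = setNames(list(setNames(fr, comps)), peptide),
    mass_error_sd = mass_error_sd,
    n_decoys = sample(10:30, 1L), n_decoy_ladders = sample(2:4, 1L),
    avoid_masses = build_candidate_db(peptide)$mono_mass,
    seed = seed + 10000L
  )
}

# Exact-mass feature table for a list of compositions on one backbone.
ladder_table <- function(peptide, comps, base_rt = 720,
                         rt_step = 2, intensities = NULL) {
  masses <- glycopeptide_mass(rep(peptide, length(comps)), comps)
  if (is.null(intensities)) intensities <- rep(1e5, length(comps))
  feature_table(neutral_mass = masses,
                rt = base_rt + rt_step * seq_along(comps),
                intensity = intensities)
}
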