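# Synthetic LC-MS1 feature tables with planted ground truth: glycoform
# ladders with residue-specific retention shifts, mass error, decoy ladders
# and scatter decoys, and optional retention-time peak splitting.

#' Specify a synthetic feature table
#'
#' Defines planted glycoprofiles and nuisance structure for the generator.
#' Defaults emulate a tryptic IgG Fc glycopeptide map on a benchtop TOF:
#' small residue-specific retention shifts (sialylation large), ~2 mDa mass
#' error, and decoys that are rejection-sampled at least
#' \code{decoy_min_gap} Da away from every residue ladder of planted nodes
#' so they can never join a planted network.
#'
#' @param peptides Data.frame with columns \code{sequence} and
#'   \code{base_rt} (seconds).
#' @param profiles Named list (by sequence) of named numeric vectors:
#'   composition short form -> fractional abundance; each must sum to 1.
#' @param rt_shift Named numeric: retention shift (s) added per residue
#'   count (\code{hexnac, hex, fuc, neuac, neugc}).
#' @param rt_jitter_sd Retention jitter SD (s).
#' @param mass_error_sd Mass error SD (Da).
#' @param intensity_total Total intensity per peptide (arbitrary units).
#' @param intensity_cv Multiplicative intensity noise (lognormal sdlog);
#'   0 = noise-free.
#' @param n_decoys Number of scatter decoy features.
#' @param n_decoy_ladders Number of decoy ladders (connectable clusters
#'   whose reference mass matches no candidate).
#' @param decoy_ladder_size Integer range of ladder sizes.
#' @param decoy_mass_range,decoy_ladder_mass_range,decoy_rt_range Sampling
#'   ranges for decoys (Da / Da / s).
#' @param split_peak_prob Probability that a planted glycoform is emitted
#'   as two retention-split features (intensities split 0.65/0.35).
#' @param split_rt_offset Retention offset between split peaks (s).
#' @param avoid_masses Extra masses (e.g. a candidate database) that decoy
#'   ladder reference masses must keep clear of.
#' @param decoy_min_gap Minimum distance (Da) between a decoy mass and any
#'   planted/decoy residue ladder.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(peptides, profiles,
                           rt_shift = c(hexnac = 2, hex = 3, fuc = 5,
                                        neuac = 120, neugc = 120),
                           rt_jitter_sd = 2, mass_error_sd = 0.002,
                           intensity_total = 1e7, intensity_cv = 0,
                           n_decoys = 0, n_decoy_ladders = 0,
                           decoy_ladder_size = c(3L, 6L),
                           decoy_mass_range = c(800, 3400),
                           decoy_ladder_mass_range = c(1400, 3300),
                           decoy_rt_range = c(200, 1600),
                           split_peak_prob = 0, split_rt_offset = 8,
                           avoid_masses = numeric(0), decoy_min_gap = 0.1,
                           seed = 1L) {
  stopifnot(is.data.frame(peptides), all(c("sequence", "base_rt") %in% names(peptides)),
            all(peptides$sequence %in% names(profiles)))
  for (p in names(profiles)) {
    fr <- profiles[[p]]
    if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-9) {
      stop(sprintf("profile fractions for %s must be positive and sum to 1", p))
    }
  }
  stopifnot(mass_error_sd >= 0, intensity_cv >= 0, split_peak_prob >= 0,
            split_peak_prob <= 1)
  structure(list(peptides = peptides, profiles = profiles, rt_shift = rt_shift,
                 rt_jitter_sd = rt_jitter_sd, mass_error_sd = mass_error_sd,
                 intensity_total = intensity_total, intensity_cv = intensity_cv,
                 n_decoys = n_decoys, n_decoy_ladders = n_decoy_ladders,
                 decoy_ladder_size = as.integer(decoy_ladder_size),
                 decoy_mass_range = decoy_mass_range,
                 decoy_ladder_mass_range = decoy_ladder_mass_range,
                 decoy_rt_range = decoy_rt_range,
                 split_peak_prob = split_peak_prob,
                 split_rt_offset = split_rt_offset,
                 avoid_masses = avoid_masses, decoy_min_gap = decoy_min_gap,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# TRUE when mass m sits at least gap away from every mass in `occupied`
# and from every residue-delta offset of those masses.
.clear_of_ladders <- function(m, occupied, deltas, gap) {
  if (!length(occupied)) return(TRUE)
  d <- abs(occupied - m)
  if (any(d < gap)) return(FALSE)
  for (dl in deltas) if (any(abs(d - dl) < gap)) return(FALSE)
  TRUE
}

#' Generate a synthetic feature table with ground truth
#'
#' Emits one feature per (peptide, composition) — or two when the peak is
#' split — with mass = exact glycopeptide mass + Gaussian error, retention
#' = peptide base + per-residue shifts + jitter, intensity proportional to
#' the planted fraction; plus decoy ladders and scatter decoys. Fully
#' deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A list: \code{features} (a [feature_table()]), \code{truth}
#'   (data.frame with \code{feature_id}, \code{kind}
#'   (\code{glycoform}/\code{decoy_ladder}/\code{decoy}), \code{peptide},
#'   \code{composition}, \code{true_mass}, \code{fraction},
#'   \code{ladder_id}) and \code{spec}.
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  deltas <- c(GLYCAN_RESIDUES, hexhexnac = unname(GLYCAN_RESIDUES["hexnac"] +
                                                    GLYCAN_RESIDUES["hex"]))
  rows <- list()
  occupied <- numeric(0)  # exact masses of all planted/ladder nodes
  for (pi in seq_len(nrow(spec$peptides))) {
    seqn <- spec$peptides$sequence[pi]
    base_rt <- spec$peptides$base_rt[pi]
    prof <- spec$profiles[[seqn]]
    comps <- names(prof)
    counts <- parse_composition(comps)
    true_mass <- glycopeptide_mass(rep(seqn, length(comps)), comps)
    occupied <- c(occupied, true_mass)
    shift <- as.numeric(counts[, names(spec$rt_shift), drop = FALSE] %*%
                          spec$rt_shift)
    for (ci in seq_along(comps)) {
      inten <- prof[[ci]] * spec$intensity_total
      if (spec$intensity_cv > 0) inten <- inten * exp(stats::rnorm(1L, 0, spec$intensity_cv))
      rt0 <- base_rt + shift[ci] + stats::rnorm(1L, 0, spec$rt_jitter_sd)
      split <- stats::runif(1L) < spec$split_peak_prob
      parts <- if (split) c(0.65, 0.35) else 1
      offs <- if (split) c(-0.5, 0.5) * spec$split_rt_offset else 0
      for (k in seq_along(parts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          neutral_mass = true_mass[ci] + stats::rnorm(1L, 0, spec$mass_error_sd),
          rt = rt0 + offs[k], intensity = inten * parts[k],
          kind = "glycoform", peptide = seqn, composition = comps[ci],
          true_mass = true_mass[ci], fraction = prof[[ci]],
          ladder_id = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  ladder_steps <- deltas[c("hexnac", "hex", "fuc")]
  for (li in seq_len(spec$n_decoy_ladders)) {
    repeat {
      base <- stats::runif(1L, spec$decoy_ladder_mass_range[1L],
                           spec$decoy_ladder_mass_range[2L])
      size <- sample(spec$decoy_ladder_size[1L]:spec$decoy_ladder_size[2L], 1L)
      steps <- sample(ladder_steps, size - 1L, replace = TRUE)
      masses <- base + cumsum(c(0, steps))
      ok <- all(vapply(masses, .clear_of_ladders, logical(1L),
                       occupied = occupied, deltas = deltas,
                       gap = spec$decoy_min_gap)) &&
        (!length(spec$avoid_masses) ||
           min(abs(spec$avoid_masses - base)) >= spec$decoy_min_gap)
      if (ok) break
    }
    occupied <- c(occupied, masses)
    rt0 <- stats::runif(1L, spec$decoy_rt_range[1L], spec$decoy_rt_range[2L])
    rts <- rt0 + 4 * seq_along(masses) + stats::rnorm(length(masses), 0, 1)
    for (k in seq_along(masses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        neutral_mass = masses[k] + stats::rnorm(1L, 0, spec$mass_error_sd),
        rt = rts[k],
        intensity = stats::runif(1L, 0.001, 0.05) * spec$intensity_total,
        kind = "decoy_ladder", peptide = NA_character_,
        composition = NA_character_, true_mass = masses[k],
        fraction = NA_real_, ladder_id = li, stringsAsFactors = FALSE)
    }
  }
  for (di in seq_len(spec$n_decoys)) {
    repeat {
      m <- stats::runif(1L, spec$decoy_mass_range[1L], spec$decoy_mass_range[2L])
      if (.clear_of_ladders(m, occupied, deltas, spec$decoy_min_gap)) break
    }
    occupied <- c(occupied, m)
    rows[[length(rows) + 1L]] <- data.frame(
      neutral_mass = m,
      rt = stats::runif(1L, spec$decoy_rt_range[1L], spec$decoy_rt_range[2L]),
      intensity = stats::runif(1L, 0.0005, 0.02) * spec$intensity_total,
      kind = "decoy", peptide = NA_character_, composition = NA_character_,
      true_mass = m, fraction = NA_real_, ladder_id = NA_integer_,
      stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  all_rows$feature_id <- seq_len(nrow(all_rows))
  features <- feature_table(neutral_mass = all_rows$neutral_mass,
                            rt = all_rows$rt, intensity = all_rows$intensity,
                            feature_id = all_rows$feature_id)
  truth <- all_rows[, c("feature_id", "kind", "peptide", "composition",
                        "true_mass", "fraction", "ladder_id")]
  list(features = features, truth = truth, spec = spec)
}

#' Planted serum IgG1 Fc glycoprofile
#'
#' Fractional glycoform abundances planted on EEQYNSTYR by the default
#' fixtures: the dominant agalacto/galactosylated core-fucosylated forms of
#' serum IgG1 plus minor sialylated, bisecting-type, afucosylated and
#' high-mannose forms, and a trace N3H5 hybrid that bridges Man5 into the
#' residue ladder.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
igg1_profile <- function() {
  c(N4H3 = 2.5, N4H3F1 = 21.5, N3H4F1 = 2.0, N4H4F1 = 36.782,
    N5H3F1 = 4.0, N4H5F1 = 19.284, N5H4F1 = 4.0, N4H4F1S1 = 5.0,
    N4H5F1S1 = 3.0, N2H5 = 0.8, N4H5 = 0.7, N3H5 = 0.434) / 100
}

#' Planted serum IgG2 Fc glycoprofile
#'
#' Fractional glycoform abundances planted on EEQFNSTFR, with the truncated
#' N3H3F1 form as the lowest-mass (reference) glycoform.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
igg2_profile <- function() {
  c(N3H3F1 = 1.5, N4H3 = 2.0, N4H3F1 = 35.0, N3H4F1 = 2.0, N4H4F1 = 33.368,
    N4H5F1 = 14.222, N5H3F1 = 3.0, N5H4F1 = 2.5, N4H4F1S1 = 4.0,
    N4H5F1S1 = 2.41) / 100
}

#' Serum-IgG-like benchmark fixture
#'
#' A canned [synthetic_spec()] mimicking the structure of a tryptic serum
#' IgG feature map: two assignable glycopeptide networks (IgG1 EEQYNSTYR
#' eluting near 12 min, IgG2 EEQFNSTFR near 18 min) among 16 decoy ladders
#' and scatter decoys, for 18 connectable clusters in total of which
#' exactly two have a reference mass matching the default candidate
#' database.
#'
#' @param seed Integer seed.
#' @param intensity_cv Multiplicative intensity noise (default 0).
#' @param mass_error_sd Mass error SD in Da.
#' @return A \code{synthetic_spec}.
#' @export
fig_fixture_serum_igg <- function(seed = 1L, intensity_cv = 0,
                                  mass_error_sd = 0.002) {
  peptides <- c("EEQYNSTYR", "EEQFNSTFR")
  synthetic_spec(
    peptides = data.frame(sequence = peptides, base_rt = c(720, 1080),
                          stringsAsFactors = FALSE),
    profiles = list(EEQYNSTYR = igg1_profile(), EEQFNSTFR = igg2_profile()),
    mass_error_sd = mass_error_sd, intensity_cv = intensity_cv,
    n_decoys = 40, n_decoy_ladders = 16, split_peak_prob = 0.15,
    avoid_masses = build_candidate_db(peptides)$mono_mass,
    seed = seed
  )
}
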