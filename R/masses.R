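# Monoisotopic mass arithmetic for peptide backbones, glycan compositions and
# glycopeptides, and construction of the glycopeptide candidate database.

# Standard monoisotopic residue masses (Da) of the 20 canonical amino acids.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.0105646

# Monosaccharide residue (dehydrated) monoisotopic masses (Da).
GLYCAN_RESIDUES <- c(
  hexnac = 203.07937,  # N-acetylhexosamine (GlcNAc/GalNAc)
  hex    = 162.05282,  # hexose (Man/Gal/Glc)
  fuc    = 146.05791,  # deoxyhexose (fucose)
  neuac  = 291.09542,  # N-acetylneuraminic acid
  neugc  = 307.09033   # N-glycolylneuraminic acid
)

# Short-form letters of the composition grammar, in canonical print order.
COMP_LETTERS <- c(N = "hexnac", H = "hex", F = "fuc", S = "neuac", G = "neugc")

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.02146 Da), the standard fixed
#' modification after iodoacetamide alkylation.
#'
#' @return Named numeric vector of per-residue mass shifts in Da.
#' @export
default_fixed_mods <- function() c(C = 57.02146)

#' Monoisotopic mass of a peptide backbone
#'
#' Sums canonical residue masses plus one water, plus any applicable fixed
#' modifications. Vectorised over sequences.
#'
#' @param sequence Character vector of uppercase one-letter amino acid
#'   sequences.
#' @param fixed_mods Named numeric vector mapping residue letters to mass
#'   shifts in Da; applied once per occurrence of the residue. Default:
#'   carbamidomethyl-C.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' peptide_mass("EEQYNSTYR")  # 1188.505
#' @export
peptide_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  stopifnot(is.character(sequence), length(sequence) >= 1L)
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) stop("peptide sequence must be non-empty")
    res <- strsplit(s, "")[[1L]]
    bad <- which(!(res %in% names(AA_MONO)))
    if (length(bad)) {
      stop(sprintf("unknown residue '%s' at position %d in '%s'",
                   res[bad[1L]], bad[1L], s))
    }
    m <- sum(AA_MONO[res]) + MASS_WATER
    if (length(fixed_mods)) {
      hit <- res[res %in% names(fixed_mods)]
      if (length(hit)) m <- m + sum(fixed_mods[hit])
    }
    m
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Parse glycan composition short forms
#'
#' Parses compositions written in the N/H/F/S/G count grammar (HexNAc,
#' Hex, Fuc, NeuAc, NeuGc), e.g. \code{"N4H5F1S1"}. An empty string is the
#' zero composition. Letters may appear in any order but at most once.
#'
#' @param text Character vector of composition short forms.
#' @return Integer matrix with one row per input and columns
#'   \code{hexnac, hex, fuc, neuac, neugc}.
#' @examples
#' parse_composition("N4H3")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text))
  out <- matrix(0L, nrow = length(text), ncol = 5L,
                dimnames = list(text, unname(COMP_LETTERS)))
  for (i in seq_along(text)) {
    s <- text[[i]]
    if (is.na(s)) stop("composition must not be NA")
    if (!nzchar(s)) next
    if (!grepl("^([NHFSG][0-9]+)+$", s)) {
      ok <- regmatches(s, regexpr("^([NHFSG][0-9]+)*", s))[[1]]
      stop(sprintf("malformed composition '%s' at position %d",
                   s, nchar(ok) + 1L))
    }
    toks <- regmatches(s, gregexpr("[NHFSG][0-9]+", s))[[1L]]
    letters <- substr(toks, 1L, 1L)
    if (anyDuplicated(letters)) {
      stop(sprintf("composition '%s' repeats residue letter '%s'",
                   s, letters[duplicated(letters)][1L]))
    }
    counts <- as.integer(substring(toks, 2L))
    out[i, COMP_LETTERS[letters]] <- counts
  }
  out
}

#' Format glycan compositions canonically
#'
#' Inverse of [parse_composition()]: writes counts in N, H, F, S, G order and
#' omits zero-count residues. The zero composition formats as \code{""}.
#'
#' @param counts Integer matrix (or single named vector) with columns
#'   \code{hexnac, hex, fuc, neuac, neugc}.
#' @return Character vector of canonical short forms.
#' @export
format_composition <- function(counts) {
  counts <- .as_comp_matrix(counts)
  unname(apply(counts, 1L, function(x) {
    nz <- x > 0L
    paste0(names(COMP_LETTERS)[nz], x[nz], collapse = "")
  }))
}

.as_comp_matrix <- function(counts) {
  if (is.character(counts)) return(parse_composition(counts))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  counts <- counts[, unname(COMP_LETTERS), drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("composition counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of count times monosaccharide residue mass; the zero composition has
#' mass 0.
#'
#' @param composition Character vector of short forms (see
#'   [parse_composition()]) or a counts matrix.
#' @return Numeric vector of masses (Da).
#' @examples
#' composition_mass("N4H3")  # 1298.476
#' @export
composition_mass <- function(composition) {
  m <- .as_comp_matrix(composition)
  as.numeric(m %*% GLYCAN_RESIDUES[colnames(m)])
}

#' Monoisotopic mass of a glycopeptide
#'
#' Exactly \code{peptide_mass(sequence) + composition_mass(composition)}:
#' neutral masses throughout, no charge handling.
#'
#' @inheritParams peptide_mass
#' @inheritParams composition_mass
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' glycopeptide_mass("EEQYNSTYR", "N4H3")  # 2486.981
#' @export
glycopeptide_mass <- function(sequence, composition,
                              fixed_mods = default_fixed_mods()) {
  peptide_mass(sequence, fixed_mods) + composition_mass(composition)
}

#' Default mammalian N-glycan composition library
#'
#' Combinatorially generated compositions covering complex/hybrid and
#' high-mannose mammalian N-glycans: 2--7 HexNAc, 3--12 Hex, 0--2 Fuc,
#' 0--4 NeuAc with NeuAc limited by antenna count (NeuAc <= HexNAc - 2);
#' high-mannose structures (2 HexNAc, 4--12 Hex) fall inside the grid.
#' NeuGc is excluded by default.
#'
#' @return A data.frame with columns \code{composition} (canonical short
#'   form) and \code{glycan_mass} (Da), sorted by mass.
#' @export
default_glycan_library <- function() {
  grid <- expand.grid(hexnac = 2:7, hex = 3:12, fuc = 0:2, neuac = 0:4,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$neuac <= pmax(grid$hexnac - 2L, 0L), , drop = FALSE]
  m <- cbind(as.matrix(grid), neugc = 0L)
  comp <- format_composition(m)
  out <- data.frame(composition = comp,
                    glycan_mass = composition_mass(m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$glycan_mass, out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a glycan composition library from CSV
#'
#' Expects a column of composition short forms (named \code{composition}, or
#' the first column); an optional \code{name} column is carried through.
#'
#' @param path Path to the CSV file.
#' @return A data.frame as from [default_glycan_library()].
#' @export
read_glycan_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- if ("composition" %in% names(df)) "composition" else names(df)[1L]
  comp <- as.character(df[[col]])
  out <- data.frame(composition = format_composition(comp),
                    glycan_mass = composition_mass(comp),
                    stringsAsFactors = FALSE)
  if ("name" %in% names(df)) out$name <- df$name
  out <- out[order(out$glycan_mass, out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the glycopeptide candidate database
#'
#' The Cartesian product of peptide backbones and glycan compositions, each
#' candidate's neutral mass being the peptide mass plus the glycan mass.
#' Duplicate compositions in the library are removed first.
#'
#' @param peptides Character vector of peptide sequences.
#' @param glycan_library A data.frame with a \code{composition} column (see
#'   [default_glycan_library()]), or a character vector of short forms.
#' @param fixed_mods Passed to [peptide_mass()].
#' @return A data.frame with columns \code{peptide}, \code{composition},
#'   \code{mono_mass}, sorted ascending by \code{mono_mass}.
#' @export
build_candidate_db <- function(peptides, glycan_library = default_glycan_library(),
                               fixed_mods = default_fixed_mods()) {
  if (is.character(glycan_library)) {
    glycan_library <- data.frame(composition = glycan_library,
                                 stringsAsFactors = FALSE)
  }
  if (length(peptides) < 1L || nrow(glycan_library) < 1L) {
    stop("need at least one peptide and one glycan composition")
  }
  comp <- format_composition(as.character(glycan_library$composition))
  comp <- comp[!duplicated(comp)]
  pep_mass <- peptide_mass(peptides, fixed_mods)
  gly_mass <- composition_mass(comp)
  db <- data.frame(
    peptide = rep(peptides, each = length(comp)),
    composition = rep(comp, times = length(peptides)),
    mono_mass = rep(pep_mass, each = length(comp)) + rep(gly_mass, length(peptides)),
    stringsAsFactors = FALSE
  )
  db <- db[order(db$mono_mass, db$peptide, db$composition), , drop = FALSE]
  rownames(db) <- NULL
  db
}
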