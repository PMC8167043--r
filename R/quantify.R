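# Glycoform relative abundance per peptide backbone and glycosylation
# attribute roll-ups.

#' Merge retention-time-split peaks
#'
#' A glycoform sometimes appears as two features with slightly different
#' retention times. Rows of an assignment table sharing
#' (peptide, composition) are collapsed into one quantitation row with
#' summed intensity, an intensity-weighted mean retention time, and the
#' contributing feature ids kept as provenance. Only \code{assigned} rows
#' are merged; other statuses pass through untouched.
#'
#' @param assignments Assignment data.frame from [propagate()] /
#'   [assign_all()].
#' @return A data.frame with columns \code{peptide}, \code{composition},
#'   \code{intensity}, \code{rt}, \code{n_features}, \code{feature_ids}.
#' @export
merge_split_peaks <- function(assignments) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(a) == 0L) {
    return(data.frame(peptide = character(0), composition = character(0),
                      intensity = numeric(0), rt = numeric(0),
                      n_features = integer(0), feature_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(a$peptide, a$composition, sep = "|")
  idx <- split(seq_len(nrow(a)), key)
  rows <- lapply(idx, function(i) {
    tot <- sum(a$intensity[i])
    data.frame(peptide = a$peptide[i[1L]], composition = a$composition[i[1L]],
               intensity = tot,
               rt = if (tot > 0) sum(a$rt[i] * a$intensity[i]) / tot else mean(a$rt[i]),
               n_features = length(i),
               feature_ids = paste(sort(a$feature_id[i]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide, composition_mass(out$composition),
                   out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Glycoform relative abundance
#'
#' Relative abundance of a glycoform is its intensity divided by the summed
#' intensity of all quantified glycoforms within the scope, times 100.
#' Default scope normalises within each peptide backbone; \code{"all"}
#' normalises over the whole sample.
#'
#' @param merged Output of [merge_split_peaks()].
#' @param scope \code{"peptide"} (default) or \code{"all"}.
#' @return A \code{glyco_profile}: the input with a
#'   \code{relative_abundance} column (percent; sums to 100 within each
#'   scope group).
#' @export
relative_abundance <- function(merged, scope = c("peptide", "all")) {
  scope <- match.arg(scope)
  if (nrow(merged) == 0L) stop("no assigned glycoforms to quantify")
  grp <- if (scope == "peptide") merged$peptide else rep("all", nrow(merged))
  tot <- tapply(merged$intensity, grp, sum)
  if (any(tot <= 0)) stop("zero total intensity in scope group")
  out <- merged
  out$relative_abundance <- 100 * merged$intensity / as.numeric(tot[grp])
  class(out) <- c("glyco_profile", "data.frame")
  attr(out, "scope") <- scope
  out
}

#' Default glycosylation attribute rules
#'
#' Composition predicates for the standard IgG Fc attributes. These are
#' composition-level naming conventions, not structural proofs (an extra
#' HexNAc is *called* bisecting in the biantennary IgG context):
#' fucosylation Fuc >= 1; sialylation NeuAc + NeuGc >= 1; high mannose
#' HexNAc == 2 and Hex >= 5; galactosylation HexNAc >= 3 and Hex >= 4
#' (complex/hybrid with at least one galactose); bisecting HexNAc >= 5 and
#' Hex <= 5 and not high mannose.
#'
#' @return Named list of predicate functions over a counts row
#'   (named integer vector with \code{hexnac, hex, fuc, neuac, neugc}).
#' @export
default_attribute_rules <- function() {
  list(
    fucosylation = function(x) x[["fuc"]] >= 1L,
    sialylation = function(x) x[["neuac"]] + x[["neugc"]] >= 1L,
    galactosylation = function(x) x[["hexnac"]] >= 3L && x[["hex"]] >= 4L,
    bisecting = function(x) x[["hexnac"]] >= 5L && x[["hex"]] <= 5L,
    high_mannose = function(x) x[["hexnac"]] == 2L && x[["hex"]] >= 5L
  )
}

#' Glycosylation attribute roll-up
#'
#' Per attribute and peptide, the summed relative abundance of glycoforms
#' whose composition satisfies the attribute predicate.
#'
#' @param profile A \code{glyco_profile} from [relative_abundance()].
#' @param rules Named list of predicates, as [default_attribute_rules()].
#' @return A data.frame with columns \code{peptide}, \code{attribute},
#'   \code{relative_abundance} (percent).
#' @export
attribute_rollup <- function(profile, rules = default_attribute_rules()) {
  counts <- parse_composition(profile$composition)
  peptides <- unique(profile$peptide)
  rows <- list()
  for (p in peptides) {
    sel <- profile$peptide == p
    for (att in names(rules)) {
      hit <- vapply(which(sel), function(i) isTRUE(rules[[att]](counts[i, ])),
                    logical(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = p, attribute = att,
        relative_abundance = sum(profile$relative_abundance[sel][hit]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Longitudinal tidy table across samples
#'
#' Stacks per-sample glycoform profiles (and attribute summaries) into one
#' long table and adds group means and standard errors across replicates,
#' for monitoring glycosylation over a bioprocess time course.
#'
#' @param profiles Named list of \code{glyco_profile} objects (names =
#'   sample ids).
#' @param metadata Data.frame with columns \code{sample} and any grouping
#'   columns (e.g. \code{day}, \code{condition}); one row per profile.
#' @param groups Character vector of metadata columns defining replicate
#'   groups (default: all metadata columns except \code{sample}).
#' @param rules Attribute rules; set \code{NULL} to skip attribute rows.
#' @return A long data.frame with columns \code{sample}, the metadata
#'   columns, \code{peptide}, \code{measure} (\code{"glycoform"} or
#'   \code{"attribute"}), \code{key} (composition or attribute name),
#'   \code{percent}, \code{group_mean} and \code{group_se} (\code{NA} for
#'   singleton groups).
#' @export
longitudinal_table <- function(profiles, metadata,
                               groups = setdiff(names(metadata), "sample"),
                               rules = default_attribute_rules()) {
  stopifnot(length(profiles) >= 1L, all(names(profiles) %in% metadata$sample))
  peps <- lapply(profiles, function(p) sort(unique(p$peptide)))
  if (length(unique(vapply(peps, paste, character(1L), collapse = ","))) > 1L) {
    warning("peptide keys differ across samples; using outer join")
  }
  rows <- list()
  for (s in names(profiles)) {
    pr <- profiles[[s]]
    md <- metadata[match(s, metadata$sample), , drop = FALSE]
    base <- data.frame(sample = s, md[, groups, drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
    rows[[length(rows) + 1L]] <- cbind(
      base[rep(1L, nrow(pr)), , drop = FALSE],
      data.frame(peptide = pr$peptide, measure = "glycoform",
                 key = pr$composition, percent = pr$relative_abundance,
                 stringsAsFactors = FALSE))
    if (!is.null(rules)) {
      at <- attribute_rollup(pr, rules)
      rows[[length(rows) + 1L]] <- cbind(
        base[rep(1L, nrow(at)), , drop = FALSE],
        data.frame(peptide = at$peptide, measure = "attribute",
                   key = at$attribute, percent = at$relative_abundance,
                   stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  gkey <- do.call(paste, c(out[, c(groups, "peptide", "measure", "key"), drop = FALSE],
                           sep = "|"))
  out$group_mean <- stats::ave(out$percent, gkey, FUN = mean)
  out$group_se <- stats::ave(out$percent, gkey, FUN = function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  rownames(out) <- NULL
  out
}
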