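mk_assignments <- function(peptide, composition, intensity,
                           rt = NULL, status = "assigned") {
  n <- length(composition)
  data.frame(feature_id = seq_len(n), peptide = peptide,
             composition = composition, status = status,
             neutral_mass = glycopeptide_mass(rep(peptide, n), composition),
             rt = if (is.null(rt)) 700 + seq_len(n) else rt,
             intensity = intensity, network_id = 1L,
             mass_error_da = 0, stringsAsFactors = FALSE)
}

test_that("retention-split duplicates merge into one summed row", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3F1", "N4H3F1", "N4H4F1"),
                      intensity = c(3e5, 1e5, 2e5), rt = c(718, 726, 730))
  m <- merge_split_peaks(a)
  expect_equal(nrow(m), 2L)
  row <- m[m$composition == "N4H3F1", ]
  expect_equal(row$intensity, 4e5)
  expect_equal(row$n_features, 2L)
  expect_equal(row$feature_ids, "1;2")
  expect_equal(row$rt, (718 * 3e5 + 726 * 1e5) / 4e5)
})

test_that("merging without duplicates is the identity on intensities", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3", "N4H4F1"), intensity = c(1, 2))
  m <- merge_split_peaks(a)
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$intensity), c(1, 2))
})

test_that("with forced peak splitting, merged rows equal distinct glycoforms", {
  spec <- fig_fixture_serum_igg(seed = 21)
  spec$split_peak_prob <- 1
  sim <- generate_features(spec)
  fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
  n_glyco <- length(igg1_profile()) + length(igg2_profile())
  expect_equal(fit$counts[["nodes_assigned"]], 2L * n_glyco)
  expect_equal(nrow(fit$merged), n_glyco)
})

test_that("relative abundance is intensity over scope total times 100", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3", "N4H4F1"), intensity = c(60, 40))
  pr <- relative_abundance(merge_split_peaks(a))
  expect_equal(sort(pr$relative_abundance), c(40, 60))
  one <- relative_abundance(merge_split_peaks(
    mk_assignments("EEQYNSTYR", "N4H3", 5)))
  expect_equal(one$relative_abundance, 100)
  zero <- mk_assignments("EEQYNSTYR", c("N4H3", "N4H4F1"), intensity = c(0, 0))
  expect_error(relative_abundance(merge_split_peaks(zero)), "zero total")
})

test_that("profiles normalise to 100 percent within each peptide", {
  sim <- generate_features(fig_fixture_serum_igg(seed = 1, intensity_cv = 0.05))
  fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
  sums <- tapply(fit$profile$relative_abundance, fit$profile$peptide, sum)
  expect_equal(as.numeric(sums), rep(100, 2L), tolerance = 1e-12)
  expect_true(all(fit$profile$relative_abundance >= 0 &
                    fit$profile$relative_abundance <= 100))
})

test_that("percentages are invariant to a global intensity rescaling", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3", "N4H4F1", "N4H5F1"),
                      intensity = c(10, 25, 65))
  p1 <- relative_abundance(merge_split_peaks(a))
  a$intensity <- a$intensity * 137.5
  p2 <- relative_abundance(merge_split_peaks(a))
  expect_equal(p1$relative_abundance, p2$relative_abundance)
})

test_that("merging commutes with normalisation", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3F1", "N4H3F1", "N4H4F1"),
                      intensity = c(3e5, 1e5, 2e5))
  merged_then <- relative_abundance(merge_split_peaks(a))
  # normalise at feature level, then sum percentages per glycoform
  pct <- 100 * a$intensity / sum(a$intensity)
  expect_equal(merged_then$relative_abundance[
    merged_then$composition == "N4H3F1"], sum(pct[1:2]))
})

test_that("attribute roll-ups apply the composition predicates", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3F1", "N4H3", "N2H5"),
                      intensity = c(50, 30, 20))
  at <- attribute_rollup(relative_abundance(merge_split_peaks(a)))
  get <- function(name) at$relative_abundance[at$attribute == name]
  expect_equal(get("fucosylation"), 50)
  expect_equal(get("high_mannose"), 20)
  expect_equal(get("sialylation"), 0)
  expect_equal(get("galactosylation"), 0)
  expect_true(all(at$relative_abundance <= 100))
})

test_that("an afucosylated profile rolls up to zero fucosylation", {
  a <- mk_assignments("EEQYNSTYR", c("N4H3", "N4H4", "N2H6"),
                      intensity = c(1, 1, 1))
  at <- attribute_rollup(relative_abundance(merge_split_peaks(a)))
  expect_equal(at$relative_abundance[at$attribute == "fucosylation"], 0)
})

test_that("attribute percent agrees between row-filter and intensity routes", {
  sim <- generate_features(fig_fixture_serum_igg(seed = 12))
  fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
  pr <- fit$profile
  counts <- parse_composition(pr$composition)
  for (p in unique(pr$peptide)) {
    sel <- pr$peptide == p
    fuc <- counts[sel, "fuc"] >= 1
    by_percent <- sum(pr$relative_abundance[sel][fuc])
    by_intensity <- 100 * sum(pr$intensity[sel][fuc]) / sum(pr$intensity[sel])
    expect_equal(by_percent, by_intensity, tolerance = 1e-12)
    expect_equal(fit$attributes$relative_abundance[
      fit$attributes$peptide == p &
        fit$attributes$attribute == "fucosylation"], by_percent)
  }
})

test_that("bisecting-type compositions roll up as planted", {
  pr <- relative_abundance(merge_split_peaks(mk_assignments(
    "EEQYNSTYR", names(igg1_profile()),
    intensity = unname(igg1_profile()) * 1e7)))
  at <- attribute_rollup(pr)
  get <- function(name) at$relative_abundance[at$attribute == name]
  planted <- igg1_profile() * 100
  expect_equal(get("bisecting"),
               unname(planted[["N5H3F1"]] + planted[["N5H4F1"]]),
               tolerance = 1e-9)
  expect_equal(get("high_mannose"), unname(planted[["N2H5"]]),
               tolerance = 1e-9)
  expect_equal(get("sialylation"),
               unname(planted[["N4H4F1S1"]] + planted[["N4H5F1S1"]]),
               tolerance = 1e-9)
})

test_that("longitudinal tables report group means and standard errors", {
  mk_prof <- function(p50) {
    relative_abundance(merge_split_peaks(mk_assignments(
      "EEQYNSTYR", c("N4H3", "N4H4F1"), intensity = c(p50, 100 - p50))))
  }
  profiles <- list(s1 = mk_prof(50), s2 = mk_prof(60), s3 = mk_prof(70))
  md <- data.frame(sample = c("s1", "s2", "s3"), day = 3, condition = "GE")
  lt <- longitudinal_table(profiles, md, rules = NULL)
  row <- lt[lt$key == "N4H3", ]
  expect_equal(unique(row$group_mean), 60)
  expect_equal(unique(row$group_se), 10 / sqrt(3), tolerance = 1e-9)
  # single sample: SE undefined, emitted as missing
  lt1 <- longitudinal_table(profiles["s1"], md[1L, ], rules = NULL)
  expect_true(all(is.na(lt1$group_se)))
})

test_that("a planted monotone trend survives into the group means", {
  mk_prof <- function(p) relative_abundance(merge_split_peaks(mk_assignments(
    "EEQYNSTYR", c("N4H3", "N4H4F1"), intensity = c(p, 100 - p))))
  days <- seq(3, 13, by = 2)
  samples <- list(); md <- NULL
  for (d in days) for (r in 1:2) {
    id <- sprintf("d%d_r%d", d, r)
    samples[[id]] <- mk_prof(20 + 5 * d + r)  # increasing in day
    md <- rbind(md, data.frame(sample = id, day = d, condition = "GE"))
  }
  lt <- longitudinal_table(samples, md, groups = c("day", "condition"),
                           rules = NULL)
  means <- unique(lt[lt$key == "N4H3", c("day", "group_mean")])
  expect_false(is.unsorted(means$group_mean[order(means$day)]))
})
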