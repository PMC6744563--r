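# Annotation machinery: shorthand parsing, masses, adducts, envelopes,
# ppm matching and series detection.

test_that("lipid shorthand parses to the expected elemental compositions", {
  ps <- parse_lipid_shorthand("PS(39:0)")
  expect_equal(format(ps), "C45H88NO10P")
  pi34 <- parse_lipid_shorthand("PI(34:0)")
  expect_equal(format(pi34), "C43H83O13P")
  expect_equal(format(parse_lipid_shorthand("PS(36:0)")), "C42H82NO10P")

  expect_error(parse_lipid_shorthand("PS39:0"), "malformed")
  expect_error(parse_lipid_shorthand("XX(34:1)"), "supported classes")
})

test_that("monoisotopic masses reproduce printed four-decimal values", {
  expect_equal(round_half_up(monoisotopic_mass("PS(39:0)"), 4), 833.6146)
  expect_equal(round_half_up(monoisotopic_mass("PI(34:0)"), 4), 838.5571)
  # homologue arithmetic: PS(36:0) is PS(39:0) minus 3 x CH2
  expect_equal(monoisotopic_mass("PS(36:0)"),
               monoisotopic_mass("PS(39:0)") - 3 * 14.01565,
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass(c(C = 0)), 0)
  expect_error(monoisotopic_mass(c(Xx = 1)), "unsupported element")
})

test_that("CH2 homology holds across all supported lipid classes", {
  for (cls in c("PA", "PC", "PE", "PG", "PI", "PS")) {
    for (d in 0:2) {
      m1 <- monoisotopic_mass(sprintf("%s(%d:%d)", cls, 34, d))
      m2 <- monoisotopic_mass(sprintf("%s(%d:%d)", cls, 35, d))
      expect_equal(m2 - m1, 14.01565, tolerance = 1e-6,
                   label = sprintf("%s C34->C35 d=%d", cls, d))
    }
  }
})

test_that("adduct m/z reproduces printed values under the neutral-atom convention", {
  ps <- monoisotopic_mass("PS(39:0)")
  pi34 <- monoisotopic_mass("PI(34:0)")
  expect_equal(round_half_up(adduct_mz(ps, "[M+H]+"), 4), 834.6224)
  expect_equal(round_half_up(adduct_mz(ps, "[M+K]+"), 4), 872.5783)
  expect_equal(round_half_up(adduct_mz(pi34, "[M+NH4]+"), 4), 856.5915)
  # electron-corrected convention is exactly one electron lighter
  expect_equal(adduct_mz(ps, "[M+H]+", "electron"),
               adduct_mz(ps, "[M+H]+") - 0.00054857990907)
  expect_error(adduct_mz(ps, "[M+2H]2+"), "unknown adduct")
})

test_that("carbon-mode envelopes give the printed integer intensity triples", {
  ps <- isotope_envelope("PS(39:0)", mode = "carbon", n_isotopologues = 3)
  expect_equal(round_half_up(ps$relative_intensity), c(100, 49, 12))
  pi34 <- isotope_envelope("PI(34:0)", mode = "carbon", n_isotopologues = 3)
  expect_equal(round_half_up(pi34$relative_intensity), c(100, 47, 11))
  # printed spacing between consecutive isotopologues
  expect_equal(diff(ps$mz_shift), c(1.0034, 1.0034))
  expect_equal(ps$relative_intensity[1], 100)
})

test_that("carbon-mode envelope is strictly decreasing and handles no-carbon input", {
  env <- isotope_envelope(c(C = 40, H = 80), mode = "carbon",
                          n_isotopologues = 5)
  expect_true(all(diff(env$relative_intensity) < 0))
  expect_warning(e0 <- isotope_envelope(c(H = 2, O = 1), mode = "carbon",
                                        n_isotopologues = 3), "no carbon")
  expect_equal(e0$relative_intensity, 100)
})

test_that("full-mode envelope equals exhaustive isotope enumeration", {
  for (comp in list(c(C = 1, H = 4), c(C = 2, H = 2), c(S = 1, O = 2),
                    c(C = 1, N = 1, H = 3))) {
    got <- isotope_envelope(comp, mode = "full", n_isotopologues = 4)
    want <- enum_envelope(comp, n_isotopologues = 4)
    expect_equal(got$shift, want$shift)
    expect_equal(got$relative_intensity, want$relative_intensity,
                 tolerance = 1e-10)
    expect_equal(got$mz_shift, want$mz_shift, tolerance = 1e-10)
  }
})

test_that("ppm error matches the printed deltas and is exact at zero", {
  expect_equal(round_half_up(ppm_error(834.614, 834.6224), 2), -10.06)
  expect_equal(round_half_up(ppm_error(856.597, 856.5915), 2), 6.42)
  expect_equal(ppm_error(850, 850), 0)
  # sign correctness either side
  expect_true(ppm_error(850.001, 850) > 0)
  expect_true(ppm_error(849.999, 850) < 0)
})

test_that("isotopologue series detection chains 1.0034-spaced peaks", {
  s <- detect_isotopologue_series(c(834.614, 835.617))
  expect_length(s, 1)
  expect_equal(s[[1]], c(1, 2))

  s <- detect_isotopologue_series(c(872.573, 873.577, 874.576))
  expect_length(s, 1)
  expect_equal(s[[1]], 1:3)

  s <- detect_isotopologue_series(c(700.0, 705.0))
  expect_length(s, 2)
  expect_equal(lengths(s), c(1L, 1L))

  expect_error(detect_isotopologue_series(c(700, 701), tol = 0), "tol")
  expect_error(detect_isotopologue_series(c(701, 700)), "ascending")
})

test_that("candidate assignment finds the ammonium adduct of PI(34:0)", {
  hits <- assign_candidates(856.597, "PI(34:0)", ppm_threshold = 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$adduct, "[M+NH4]+")
  expect_equal(hits$isotopologue, 0)
  expect_equal(round_half_up(hits$ppm, 2), 6.42)

  exact <- adduct_mz(monoisotopic_mass("PS(39:0)"), "[M+H]+")
  hit0 <- assign_candidates(exact, "PS(39:0)")
  expect_equal(nrow(hit0), 1)
  expect_equal(hit0$ppm, 0)

  expect_equal(nrow(assign_candidates(700.0, "PS(39:0)")), 0)
  expect_error(assign_candidates(700.0, character(0)), "empty")
})

test_that("vectorised annotation agrees with the one-ion interface", {
  lib <- c("PS(39:0)", "PI(34:0)", "PC(34:1)")
  observed <- c(856.597, 834.614, 750.0)
  vec <- annotate_peaks(observed, lib)
  for (obs in observed) {
    one <- assign_candidates(obs, lib)
    sub <- vec[vec$observed == obs, , drop = FALSE]
    expect_equal(nrow(sub), nrow(one))
    if (nrow(one)) {
      expect_equal(sub$name, one$name)
      expect_equal(sub$ppm, one$ppm, tolerance = 1e-12)
    }
  }
})

test_that("envelope matching is a cosine on truncated intensity vectors", {
  expect_equal(match_envelope(c(100, 49, 12), c(100, 49, 12)), 1)
  env <- isotope_envelope("PS(39:0)", mode = "carbon")
  obs <- c(100, 40)
  manual <- sum(obs * env$relative_intensity[1:2]) /
    sqrt(sum(obs^2) * sum(env$relative_intensity[1:2]^2))
  expect_equal(match_envelope(obs, env), manual)
  # reversing a decreasing envelope strictly lowers the fit
  expect_lt(match_envelope(rev(env$relative_intensity), env),
            match_envelope(env$relative_intensity, env))
  expect_error(match_envelope(c(0, 0), env), "all zero")
})

test_that("assignment tables use the exact 13C shift for isotopologue masses", {
  tab <- assignment_table(data.frame(
    observed = c(835.617, 874.576),
    name = "PS(39:0)",
    adduct = c("[M+H]+", "[M+K]+"),
    isotopologue = c(1L, 2L)))
  expect_equal(tab$theoretical_mass, c(834.6179, 835.6213))
  expect_equal(tab$adduct_mz, c(835.6258, 874.5850))
  expect_equal(tab$delta_ppm, c(-10.53, -10.29))
})
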