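# Phantom generator: geometry, manifests, rendering.

test_that("region masks partition the grid with every pixel labelled once", {
  masks <- make_region_masks(64, 48)
  expect_named(masks$masks, c("grey_matter", "fibre_tract",
                              "cerebellar_cortex", "brainstem", "off_tissue"))
  label_count <- Reduce(`+`, lapply(masks$masks, function(m) m * 1))
  expect_true(all(label_count == 1))
  expect_equal(sum(vapply(masks$masks, sum, numeric(1))), 64 * 48)
  # deterministic: no randomness involved
  expect_identical(masks, make_region_masks(64, 48))
  # off-tissue margin exists on every border row/column
  off <- masks$masks$off_tissue
  expect_true(all(off[1, ]) && all(off[nrow(off), ]) &&
                all(off[, 1]) && all(off[, ncol(off)]))
  expect_error(make_region_masks(8, 8), "too small")
})

test_that("archetype templates are supported on their regions and disjoint", {
  masks <- make_region_masks(48, 32)
  tpl <- archetype_templates(masks)
  expect_named(tpl, archetype_names())
  # group III lives only on the cerebellar cortex
  expect_true(all(tpl$III[!masks$masks$cerebellar_cortex] == 0))
  expect_true(any(tpl$III > 0))
  # the ten group templates have pairwise disjoint supports
  for (a in as.character(as.roman(1:9))) {
    for (b in as.character(as.roman(2:10))) {
      if (a == b) next
      expect_equal(sum(tpl[[a]] > 0 & tpl[[b]] > 0), 0,
                   label = sprintf("supports %s vs %s", a, b))
    }
  }
  # off-tissue artefact is brighter outside than inside on average
  off <- masks$masks$off_tissue
  expect_gt(mean(tpl$artefact_off_tissue[off]),
            mean(tpl$artefact_off_tissue[!off]))
})

test_that("ground-truth sampling is reproducible and respects the weights", {
  lib <- default_formula_library()
  gt1 <- make_ground_truth(100, formula_table = lib, seed = 1)
  gt2 <- make_ground_truth(100, formula_table = lib, seed = 1)
  expect_identical(gt1$molecules, gt2$molecules)
  expect_false(identical(
    gt1$molecules,
    make_ground_truth(100, formula_table = lib, seed = 2)$molecules))
  expect_true(all(lengths(gt1$molecules$adducts) >= 1))

  # uniform weights over 12 archetypes: each count inside exact
  # multinomial bounds (Bonferroni across the 12 cells at level 1e-6)
  counts <- table(factor(gt1$molecules$archetype, levels = archetype_names()))
  p <- 1 / 12
  lo <- qbinom(1e-6 / 24, 100, p)
  hi <- qbinom(1 - 1e-6 / 24, 100, p)
  expect_true(all(counts >= lo & counts <= hi))

  forced <- make_ground_truth(5, archetype_weights = c(III = 1),
                              formula_table = lib, seed = 3)
  expect_true(all(forced$molecules$archetype == "III"))

  expect_error(make_ground_truth(5, formula_table = lib[0, ], seed = 1),
               "empty")
  expect_error(make_ground_truth(10^6, formula_table = lib, seed = 1),
               "only")
  expect_error(make_ground_truth(5, archetype_weights = c(III = 0.8),
                                 formula_table = lib, seed = 1),
               "sum to 1")
})

test_that("noiseless rendering reproduces envelope fractions and masses exactly", {
  masks <- make_region_masks(24, 20)
  truth <- new_ground_truth("PS(39:0)", "III", "[M+H]+", base_intensity = 50)
  ds <- render_dataset(truth, masks, noise_model(0, 0, 0), seed = 1)
  env <- isotope_envelope("PS(39:0)", mode = "carbon")

  support <- which(t(archetype_templates(masks)$III) > 0)
  s <- ds$spectra[[support[1]]]
  expect_length(s$mz, 3)
  # m/z values match the printed four-decimal theoretical adduct masses
  expect_equal(round_half_up(s$mz, 4), c(834.6224, 835.6258, 836.6291))
  # isotopologue intensity ratios equal the envelope fractions exactly
  expect_equal(s$intensity[2] / s$intensity[1],
               env$relative_intensity[2] / 100)
  expect_equal(s$intensity[3] / s$intensity[1],
               env$relative_intensity[3] / 100)
})

test_that("rendering conserves total signal and respects archetype support", {
  masks <- make_region_masks(24, 20)
  tpl <- archetype_templates(masks)
  truth <- new_ground_truth("PI(34:0)", "III", "[M+NH4]+",
                            base_intensity = 80)
  ds <- render_dataset(truth, masks, noise_model(0, 0, 0), seed = 1)
  env <- isotope_envelope("PI(34:0)", mode = "carbon")

  total <- sum(unlist(lapply(ds$spectra, `[[`, "intensity")))
  expect_equal(total, 80 * sum(tpl$III) * sum(env$relative_intensity) / 100,
               tolerance = 1e-12)
  # zero intensity outside the cerebellar mask
  img <- ion_image(ds, adduct_mz(monoisotopic_mass("PI(34:0)"), "[M+NH4]+"))
  expect_true(all(img$values[!masks$masks$cerebellar_cortex] == 0))
})

test_that("rendering is bit-identical under a fixed seed and empty truth renders empty", {
  masks <- make_region_masks(20, 16)
  truth <- new_ground_truth(c("PS(39:0)", "PC(34:1)"), c("I", "IV"),
                            list("[M+H]+", c("[M+H]+", "[M+K]+")))
  d1 <- render_dataset(truth, masks, noise_model(), seed = 5)
  d2 <- render_dataset(truth, masks, noise_model(), seed = 5)
  expect_identical(d1, d2)
  d3 <- render_dataset(truth, masks, noise_model(), seed = 6)
  expect_false(identical(d1, d3))

  blank <- new_ground_truth(character(0), character(0), list())
  db <- render_dataset(blank, masks, noise_model(0, 0, 0), seed = 1)
  expect_equal(n_pixels(db), 20 * 16)
  expect_true(all(vapply(db$spectra, function(s) length(s$mz), integer(1)) == 0))
})

test_that("rendering fails loudly for unknown adducts, naming the molecule", {
  masks <- make_region_masks(20, 16)
  truth <- new_ground_truth("PS(39:0)", "I", "[M+2H]2+")
  expect_error(render_dataset(truth, masks, noise_model(0, 0, 0), seed = 1),
               "PS\\(39:0\\).*unknown adduct")
})

test_that("picked peaks map back to planted molecules with isobar flags", {
  ph <- small_phantom(seed = 21)
  pk <- pick_peaks(average_spectrum(ph$dataset))
  matched <- match_peaks_to_truth(pk$mz, ph$truth)
  hit <- matched[!is.na(matched$molecule), ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$molecule %in% ph$truth$molecules$name))
  # species were chosen well-separated: nothing is ambiguous
  expect_false(any(hit$ambiguous))
})
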