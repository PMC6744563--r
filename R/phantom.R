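# Synthetic brain-phantom generator: region geometry, archetype spatial
# templates, ground-truth manifests and rendering to centroided spectra.
#
# The phantom emulates a sagittal-section raster: an elliptical tissue area
# containing grey matter, a fibre-tract band, a cerebellar-cortex disc and a
# brainstem disc, surrounded by an off-tissue margin. Ten molecule-group
# archetypes (I-X) are rendered on mutually disjoint sub-region supports so
# that spatially distinct groups are identifiable by cosine similarity;
# two artefact archetypes (homogeneous-everywhere and off-tissue-enriched)
# exercise the screening rules.

REGION_LABELS <- c("grey_matter", "fibre_tract", "cerebellar_cortex",
                   "brainstem", "off_tissue")

ARCHETYPES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
                "artefact_homogeneous", "artefact_off_tissue")

#' Build the phantom region masks
#'
#' Partitions a `width` x `height` pixel grid into five mutually exclusive
#' regions: grey matter, fibre tract, cerebellar cortex, brainstem and the
#' off-tissue margin (the complement of the elliptical tissue area). Purely
#' deterministic geometry.
#'
#' @param width,height grid dimensions in pixels, both >= 16.
#' @param layout template identifier; only `"default"` is defined.
#' @return object of class `region_masks`: named list of logical matrices
#'   (`height` rows x `width` cols) under `$masks`, plus `$dims = c(width,
#'   height)`.
#' @export
make_region_masks <- function(width, height, layout = "default") {
  if (width < 16 || height < 16) {
    stopf("grid too small: need width and height >= 16 to place all regions")
  }
  if (!identical(layout, "default")) stopf("unknown layout '%s'", layout)
  w <- as.integer(width); h <- as.integer(height)
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)   # x per pixel
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)  # y per pixel

  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- 0.42 * w; b <- 0.38 * h
  tissue <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  rmin <- min(w, h)
  circ <- function(x0, y0, r) (xs - x0)^2 + (ys - y0)^2 <= r^2
  cereb <- tissue & circ(0.70 * w, 0.36 * h, 0.11 * rmin)
  stem <- tissue & circ(0.74 * w, 0.66 * h, 0.09 * rmin) & !cereb
  fibre <- tissue & abs(ys - 0.56 * h) <= 0.07 * h &
    xs >= 0.18 * w & xs <= 0.62 * w & !cereb & !stem
  grey <- tissue & !cereb & !stem & !fibre

  masks <- list(grey_matter = grey, fibre_tract = fibre,
                cerebellar_cortex = cereb, brainstem = stem,
                off_tissue = !tissue)
  for (lab in REGION_LABELS) {
    if (!any(masks[[lab]])) stopf("grid too small: region '%s' is empty", lab)
  }
  structure(list(masks = masks, dims = c(w, h), layout = layout),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks> %dx%d grid:\n", x$dims[1], x$dims[2]))
  for (lab in names(x$masks)) {
    cat(sprintf("  %-18s %5d px\n", lab, sum(x$masks[[lab]])))
  }
  invisible(x)
}

#' Tissue ROI of a phantom
#'
#' @param masks a `region_masks`.
#' @return an `roi` covering all non-off-tissue pixels.
#' @export
tissue_roi <- function(masks) {
  stopifnot(inherits(masks, "region_masks"))
  new_roi(!masks$masks$off_tissue)
}

# Linear left-to-right ramp over the support of `mask`, amplitude
# `gradient` (template spans [1 - g, 1 + g] across the support's x extent).
ramped_template <- function(mask, gradient) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  x <- idx[, 2] - 1
  t <- if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else rep(0.5, length(x))
  out[idx] <- 1 + gradient * (2 * t - 1)
  out
}

#' Spatial intensity templates for the molecule archetypes
#'
#' Maps each archetype to a non-negative intensity template over the grid:
#' groups I, II, V, VI, VII and X occupy successive anterior-to-posterior
#' grey-matter bands; IV and VIII the anterior and posterior halves of the
#' fibre tract; III the cerebellar cortex; IX the brainstem.
#' `artefact_homogeneous` covers the whole grid (tissue and slide) and
#' `artefact_off_tissue` is enriched on the off-tissue margin (margin 1.0,
#' tissue 0.25). Every template is modulated by a smooth left-to-right
#' gradient of relative amplitude `gradient`.
#'
#' @param masks a `region_masks`.
#' @param gradient within-region gradient amplitude (default 0.2).
#' @return named list of numeric matrices, one per archetype.
#' @export
archetype_templates <- function(masks, gradient = 0.2) {
  stopifnot(inherits(masks, "region_masks"))
  m <- masks$masks
  h <- nrow(m$grey_matter); w <- ncol(m$grey_matter)

  # split grey matter into 6 anterior->posterior bands of near-equal area
  grey_idx <- which(m$grey_matter, arr.ind = TRUE)
  gx <- grey_idx[, 2]
  qs <- stats::quantile(gx, probs = seq(0, 1, length.out = 7), type = 1)
  grey_bands <- lapply(1:6, function(i) {
    sel <- if (i < 6) gx >= qs[i] & gx < qs[i + 1] else gx >= qs[i]
    band <- matrix(FALSE, h, w)
    band[grey_idx[sel, , drop = FALSE]] <- TRUE
    band
  })

  fibre_idx <- which(m$fibre_tract, arr.ind = TRUE)
  fx_med <- stats::median(fibre_idx[, 2])
  fibre_ant <- fibre_post <- matrix(FALSE, h, w)
  fibre_ant[fibre_idx[fibre_idx[, 2] <= fx_med, , drop = FALSE]] <- TRUE
  fibre_post[fibre_idx[fibre_idx[, 2] > fx_med, , drop = FALSE]] <- TRUE
  if (!any(fibre_post)) {  # degenerate narrow fibre band
    fibre_post <- fibre_ant
  }

  whole <- matrix(TRUE, h, w)
  off_base <- matrix(0.25, h, w)
  off_base[m$off_tissue] <- 1

  list(
    I = ramped_template(grey_bands[[1]], gradient),
    II = ramped_template(grey_bands[[2]], gradient),
    III = ramped_template(m$cerebellar_cortex, gradient),
    IV = ramped_template(fibre_ant, gradient),
    V = ramped_template(grey_bands[[3]], gradient),
    VI = ramped_template(grey_bands[[4]], gradient),
    VII = ramped_template(grey_bands[[5]], gradient),
    VIII = ramped_template(fibre_post, gradient),
    IX = ramped_template(m$brainstem, gradient),
    X = ramped_template(grey_bands[[6]], gradient),
    artefact_homogeneous = ramped_template(whole, gradient),
    artefact_off_tissue = off_base * ramped_template(whole, gradient)
  )
}

#' Noise model for phantom rendering
#'
#' @param baseline mean intensity of spurious peaks (a.u.); 0 disables them.
#' @param spread sdlog of the multiplicative log-normal perturbation of true
#'   peak intensities (mean-one); 0 disables it.
#' @param spurious_rate expected number of spurious peaks per spectrum
#'   (Poisson rate); 0 disables them.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(baseline = 2, spread = 0.25, spurious_rate = 3) {
  stopifnot(baseline >= 0, spread >= 0, spurious_rate >= 0)
  structure(list(baseline = baseline, spread = spread,
                 spurious_rate = spurious_rate), class = "noise_model")
}

#' Draw a phantom ground-truth manifest
#'
#' Samples `n_molecules` distinct species from a formula library, assigns
#' each an archetype (multinomially under `archetype_weights`), 1-2 positive
#' adducts and a log-normal base intensity. Fully reproducible under `seed`.
#'
#' @param n_molecules number of molecules (>= 1, at most the library size).
#' @param archetype_weights named probabilities over [archetype_names()];
#'   must sum to 1. Default: uniform.
#' @param formula_table formula library data.frame (see
#'   [default_formula_library()]).
#' @param seed integer seed.
#' @param raster raster metadata in micrometres (recorded, not used in math).
#' @return object of class `ground_truth` with `$molecules` (data.frame:
#'   name, formula, archetype, adducts list-column, base_intensity), `$seed`,
#'   `$raster`.
#' @export
make_ground_truth <- function(n_molecules,
                              archetype_weights = NULL,
                              formula_table = default_formula_library(),
                              seed = 1,
                              raster = 50) {
  stopifnot(n_molecules >= 1)
  if (is.null(formula_table) || nrow(formula_table) == 0) {
    stopf("formula table is empty")
  }
  if (is.null(archetype_weights)) {
    archetype_weights <- stats::setNames(
      rep(1 / length(ARCHETYPES), length(ARCHETYPES)), ARCHETYPES)
  }
  if (!all(names(archetype_weights) %in% ARCHETYPES)) {
    stopf("unknown archetype in weights; valid: %s",
          paste(ARCHETYPES, collapse = ", "))
  }
  if (abs(sum(archetype_weights) - 1) > 1e-8) {
    stopf("archetype weights must sum to 1")
  }
  if (n_molecules > nrow(formula_table)) {
    stopf("formula table has only %d species for %d molecules",
          nrow(formula_table), n_molecules)
  }
  molecules <- with_seed(seed, {
    rows <- sample.int(nrow(formula_table), n_molecules)
    arch <- sample(names(archetype_weights), n_molecules, replace = TRUE,
                   prob = archetype_weights)
    n_add <- sample(1:2, n_molecules, replace = TRUE)
    adducts <- lapply(n_add, function(k) {
      sample(names(ADDUCT_COMPOSITIONS), k)
    })
    base <- stats::rlnorm(n_molecules, meanlog = log(100), sdlog = 0.4)
    data.frame(
      name = formula_table$name[rows],
      formula = vapply(formula_table$name[rows],
                       function(nm) format(parse_lipid_shorthand(nm)),
                       character(1)),
      archetype = arch,
      adducts = I(adducts),
      base_intensity = base,
      stringsAsFactors = FALSE
    )
  })
  rownames(molecules) <- NULL
  structure(list(molecules = molecules, seed = as.integer(seed),
                 raster = raster),
            class = "ground_truth")
}

#' Archetype labels understood by the phantom
#' @return character vector of archetype names.
#' @export
archetype_names <- function() ARCHETYPES

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d molecules, seed %d\n", nrow(x$molecules),
              x$seed))
  print(table(x$molecules$archetype))
  invisible(x)
}

#' Theoretical peak table of a ground truth
#'
#' Expands the manifest to one row per (molecule, adduct, isotopologue) with
#' the theoretical m/z rendered by [render_dataset()]. Used to match picked
#' peaks back to planted molecules.
#'
#' @param truth a `ground_truth`.
#' @param n_isotopologues isotopologues per adduct (default 3).
#' @param mz_range retain only peaks inside this range.
#' @return data.frame: molecule, archetype, adduct, isotopologue, mz,
#'   relative_intensity.
#' @export
truth_peak_table <- function(truth, n_isotopologues = 3,
                             mz_range = c(700, 900)) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list()
  for (i in seq_len(nrow(truth$molecules))) {
    mol <- truth$molecules[i, ]
    mono <- monoisotopic_mass(mol$name)
    env <- isotope_envelope(mol$name, mode = "carbon",
                            n_isotopologues = n_isotopologues)
    for (ad in mol$adducts[[1]]) {
      mz0 <- adduct_mz(mono, ad)
      for (j in seq_len(nrow(env))) {
        mz <- mz0 + env$shift[j] * C13_SHIFT_EXACT
        if (mz < mz_range[1] || mz > mz_range[2]) next
        out[[length(out) + 1]] <- data.frame(
          molecule = mol$name, archetype = mol$archetype, adduct = ad,
          isotopologue = env$shift[j], mz = mz,
          relative_intensity = env$relative_intensity[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Render a phantom dataset
#'
#' Renders every molecule of the manifest onto the grid: at each pixel, one
#' centroided peak per isotopologue per adduct with intensity
#' `base * template(pixel) * envelope_fraction`, perturbed by the noise
#' model (mean-one log-normal on true peaks; Poisson-count spurious peaks at
#' uniform m/z with exponential intensity). Isotopologue m/z spacing uses
#' the exact 13C shift. Peaks outside `mz_range` are dropped. The result is
#' bit-identical for identical arguments and seed.
#'
#' @param truth a `ground_truth`.
#' @param masks a `region_masks`.
#' @param noise a `noise_model`; `noise_model(0, 0, 0)` renders noiselessly.
#' @param seed integer seed for the rendering randomness.
#' @param mz_range m/z window (default 700-900).
#' @param n_isotopologues isotopologues per adduct (default 3).
#' @param gradient within-region gradient amplitude (default 0.2).
#' @return an `ims_dataset` with one spectrum per grid pixel.
#' @export
render_dataset <- function(truth, masks, noise = noise_model(), seed = 1,
                           mz_range = c(700, 900), n_isotopologues = 3,
                           gradient = 0.2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(masks, "region_masks"),
            inherits(noise, "noise_model"))
  w <- masks$dims[1]; h <- masks$dims[2]
  npx <- w * h
  templates <- archetype_templates(masks, gradient = gradient)

  pix <- list(); mzs <- list(); ints <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(truth$molecules))) {
      mol <- truth$molecules[i, ]
      if (!mol$archetype %in% names(templates)) {
        stopf("molecule '%s': no spatial template for archetype '%s'",
              mol$name, mol$archetype)
      }
      comp <- tryCatch(parse_lipid_shorthand(mol$name),
                       error = function(e) {
                         stopf("molecule '%s': %s", mol$name, conditionMessage(e))
                       })
      mono <- monoisotopic_mass(comp)
      env <- isotope_envelope(comp, mode = "carbon",
                              n_isotopologues = n_isotopologues)
      tv <- as.vector(t(templates[[mol$archetype]]))  # row-major, x fastest
      support <- which(tv > 0)
      if (!length(support)) next
      for (ad in mol$adducts[[1]]) {
        if (!ad %in% names(ADDUCT_COMPOSITIONS)) {
          stopf("molecule '%s': unknown adduct '%s'", mol$name, ad)
        }
        mz0 <- adduct_mz(mono, ad)
        for (j in seq_len(nrow(env))) {
          mz <- mz0 + env$shift[j] * C13_SHIFT_EXACT
          if (mz < mz_range[1] || mz > mz_range[2]) next
          intensity <- mol$base_intensity * tv[support] *
            env$relative_intensity[j] / 100
          if (noise$spread > 0) {
            intensity <- intensity * stats::rlnorm(
              length(support), meanlog = -noise$spread^2 / 2,
              sdlog = noise$spread)
          }
          pix[[length(pix) + 1]] <- support
          mzs[[length(mzs) + 1]] <- rep(mz, length(support))
          ints[[length(ints) + 1]] <- intensity
        }
      }
    }
    if (noise$spurious_rate > 0 && noise$baseline > 0) {
      counts <- stats::rpois(npx, noise$spurious_rate)
      total <- sum(counts)
      if (total > 0) {
        pix[[length(pix) + 1]] <- rep(seq_len(npx), counts)
        mzs[[length(mzs) + 1]] <- stats::runif(total, mz_range[1], mz_range[2])
        ints[[length(ints) + 1]] <- stats::rexp(total, rate = 1 / noise$baseline)
      }
    }
  })

  if (length(pix)) {
    pvec <- unlist(pix); mvec <- unlist(mzs); ivec <- unlist(ints)
    ord <- order(pvec, mvec)
    pvec <- pvec[ord]; mvec <- mvec[ord]; ivec <- ivec[ord]
    # sum intensities of coincident (pixel, m/z) peaks
    key_new <- c(TRUE, diff(pvec) != 0 | diff(mvec) != 0)
    gid <- cumsum(key_new)
    mvec <- mvec[key_new]
    pvec <- pvec[key_new]
    ivec <- as.numeric(tapply(ivec, gid, sum))
    by_pixel <- split(seq_along(pvec), pvec)
  } else {
    by_pixel <- list()
  }

  spectra <- vector("list", npx)
  for (p in seq_len(npx)) {
    x <- (p - 1L) %% w
    y <- (p - 1L) %/% w
    rows <- by_pixel[[as.character(p)]]
    if (is.null(rows)) {
      spectra[[p]] <- new_spectrum(numeric(0), numeric(0), c(x, y))
    } else {
      spectra[[p]] <- new_spectrum(mvec[rows], ivec[rows], c(x, y))
    }
  }
  new_ims_dataset(spectra, dims = c(w, h), raster = truth$raster,
                  mz_range = mz_range)
}

#' Match observed peak m/z values to planted molecules
#'
#' For each observed m/z, finds the ground-truth (molecule, adduct,
#' isotopologue) peak within `tol`. Matches are marked ambiguous when a
#' peak of a *different* molecule lies within `ambiguity` of the matched
#' theoretical m/z (isobaric interference inside the ion-image window), so
#' recovery experiments can exclude them.
#'
#' @param mz numeric vector of observed m/z values (e.g. picked peaks).
#' @param truth a `ground_truth`.
#' @param tol match tolerance in Da (default 0.005).
#' @param ambiguity isobaric-exclusion radius in Da (default 0.01).
#' @param ... passed to [truth_peak_table()].
#' @return data.frame: `mz`, `molecule`, `archetype`, `adduct`,
#'   `isotopologue` (NA where unmatched), `ambiguous` (logical).
#' @export
match_peaks_to_truth <- function(mz, truth, tol = 0.005, ambiguity = 0.01,
                                 ...) {
  peaks <- truth_peak_table(truth, ...)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  out <- data.frame(mz = mz, molecule = NA_character_,
                    archetype = NA_character_, adduct = NA_character_,
                    isotopologue = NA_integer_, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mz)) {
    d <- abs(peaks$mz - mz[i])
    j <- which.min(d)
    if (d[j] > tol) next
    out$molecule[i] <- peaks$molecule[j]
    out$archetype[i] <- peaks$archetype[j]
    out$adduct[i] <- peaks$adduct[j]
    out$isotopologue[i] <- peaks$isotopologue[j]
    near <- abs(peaks$mz - peaks$mz[j]) <= ambiguity &
      peaks$molecule != peaks$molecule[j]
    out$ambiguous[i] <- any(near)
  }
  out
}

#' Construct a ground truth explicitly
#'
#' Lower-level companion to [make_ground_truth()] for designed experiments:
#' every molecule's archetype, adducts and base intensity are given rather
#' than sampled.
#'
#' @param names lipid shorthand names (may be empty for a blank phantom).
#' @param archetypes archetype label per molecule (see [archetype_names()]).
#' @param adducts list of character vectors (one per molecule), or a single
#'   adduct name recycled to all molecules.
#' @param base_intensity numeric, recycled.
#' @param seed seed recorded in the manifest.
#' @param raster raster metadata (um).
#' @return a `ground_truth`.
#' @export
new_ground_truth <- function(names, archetypes, adducts = "[M+H]+",
                             base_intensity = 100, seed = NA_integer_,
                             raster = 50) {
  n <- length(names)
  stopifnot(length(archetypes) == n)
  if (!is.list(adducts)) adducts <- rep(list(adducts), n)
  stopifnot(length(adducts) == n || n == 0)
  base_intensity <- rep_len(base_intensity, n)
  if (n > 0 && !all(archetypes %in% ARCHETYPES)) {
    stopf("unknown archetype label; valid: %s", paste(ARCHETYPES, collapse = ", "))
  }
  if (n > 0 && !all(lengths(adducts) >= 1)) {
    stopf("every molecule needs at least one adduct")
  }
  molecules <- data.frame(
    name = as.character(names),
    formula = if (n) vapply(names, function(nm) format(parse_lipid_shorthand(nm)),
                            character(1)) else character(0),
    archetype = as.character(archetypes),
    adducts = I(adducts),
    base_intensity = base_intensity,
    stringsAsFactors = FALSE)
  rownames(molecules) <- NULL
  structure(list(molecules = molecules, seed = as.integer(seed),
                 raster = raster), class = "ground_truth")
}

#' Select species with well-separated adduct m/z
#'
#' Greedily picks species from a formula library such that the full
#' isotopologue footprints of their (single-adduct) ions are at least
#' `min_gap` apart, so rendered peaks neither merge during picking nor
#' share ion-image windows. Deterministic.
#'
#' @param formula_table formula library.
#' @param n number of species required.
#' @param min_gap minimum spacing in Da between isotopologue footprints
#'   (default 2.2).
#' @param adduct the adduct whose m/z spacing is enforced.
#' @param n_isotopologues isotopologues per footprint (default 3).
#' @param mz_range admissible m/z window.
#' @return character vector of `n` species names, ascending in m/z.
#' @export
select_spaced_species <- function(formula_table, n, min_gap = 2.2,
                                  adduct = "[M+H]+", n_isotopologues = 3,
                                  mz_range = c(700, 900)) {
  mz <- vapply(formula_table$name, function(nm) {
    adduct_mz(monoisotopic_mass(nm), adduct)
  }, numeric(1))
  span <- (n_isotopologues - 1) * C13_SHIFT_EXACT
  ok <- mz >= mz_range[1] & mz + span <= mz_range[2]
  ord <- order(mz)
  ord <- ord[ok[ord]]
  chosen <- integer(0)
  last_end <- -Inf
  for (i in ord) {
    if (mz[i] > last_end + min_gap) {
      chosen <- c(chosen, i)
      last_end <- mz[i] + span
      if (length(chosen) == n) break
    }
  }
  if (length(chosen) < n) {
    stopf("library supports only %d species at min_gap %.2f Da (%d requested)",
          length(chosen), min_gap, n)
  }
  formula_table$name[chosen]
}
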