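# End-to-end pipeline: simulate -> peaks -> screen -> pca -> cluster ->
# annotate, with a validated config, stage logging and a run summary.

pipeline_defaults <- function() {
  list(
    mz_range = c(700, 900),
    input = NULL,  # imzML path; used when simulate$enabled is FALSE
    simulate = list(
      enabled = TRUE, width = 64, height = 48, n_molecules = 100,
      archetype_weights = NULL, gradient = 0.2, raster = 50,
      n_isotopologues = 3,
      noise = list(baseline = 2, spread = 0.25, spurious_rate = 3)
    ),
    peaks = list(snr = 10, width = 0.2, halfwidth = 0.004, bin_width = 0.001),
    screening = list(enabled = TRUE, enrichment = 2),
    pca = list(components = 5),
    cluster = list(threshold = 0.5, min_size = 7, linkage = "average"),
    annotate = list(enabled = TRUE, ppm = 10,
                    adducts = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+"),
                    n_isotopologues = 3)
  )
}

merge_config <- function(defaults, config, path = "") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
          paste0(path, unknown, collapse = ", "))
  }
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(config[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], config[[key]],
                                      paste0(path, key, "$"))
    } else {
      defaults[key] <- config[key]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Injects defaults for missing keys, rejects unknown keys, and range-checks
#' every threshold. The defaults pin the analysis parameters of the package:
#' peak picking at S/N 10 with 0.2 Da merge width, ion-image intervals of
#' +/- 0.004 Da in maximum mode, 5 PCA components with unit-variance
#' scaling, similarity threshold 0.5 with minimum group size 7, and a
#' 10 ppm annotation tolerance.
#'
#' @param config (possibly partial) configuration list, or a path to a YAML
#'   file holding one.
#' @return the full configuration with defaults injected.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  full <- merge_config(pipeline_defaults(), config)

  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(length(full$mz_range) == 2 && full$mz_range[1] < full$mz_range[2],
      "mz_range must be an increasing pair")
  chk(full$peaks$snr > 0, "peaks$snr must be > 0")
  chk(full$peaks$width > 0, "peaks$width must be > 0")
  chk(full$peaks$halfwidth > 0, "peaks$halfwidth must be > 0")
  chk(full$peaks$bin_width > 0, "peaks$bin_width must be > 0")
  chk(full$screening$enrichment > 0, "screening$enrichment must be > 0")
  chk(full$pca$components >= 1, "pca$components must be >= 1")
  chk(full$cluster$threshold > 0 && full$cluster$threshold < 1,
      "cluster$threshold must be inside (0, 1)")
  chk(full$cluster$min_size >= 1, "cluster$min_size must be >= 1")
  chk(full$cluster$linkage %in% c("average", "single", "complete"),
      "cluster$linkage must be average, single or complete")
  chk(full$annotate$ppm > 0, "annotate$ppm must be > 0")
  chk(all(full$annotate$adducts %in% names(ADDUCT_COMPOSITIONS)),
      "annotate$adducts contains an unknown adduct")
  if (full$simulate$enabled) {
    chk(full$simulate$width >= 16 && full$simulate$height >= 16,
        "simulate grid must be at least 16x16")
    chk(full$simulate$n_molecules >= 1, "simulate$n_molecules must be >= 1")
    nm <- full$simulate$noise
    chk(all(unlist(nm) >= 0), "noise parameters must be >= 0")
  } else {
    chk(!is.null(full$input), "input imzML path required when simulation is disabled")
  }
  full
}

# Theoretical m/z table of a formula library over adducts and isotopologues.
library_mz_table <- function(library, adducts, n_isotopologues = 3,
                             convention = "neutral") {
  names_vec <- if (is.data.frame(library)) library$name else library
  masses <- vapply(names_vec, monoisotopic_mass, numeric(1))
  grid <- expand.grid(name = names_vec, adduct = adducts,
                      isotopologue = 0:(n_isotopologues - 1),
                      stringsAsFactors = FALSE)
  grid$theoretical_mz <- vapply(seq_len(nrow(grid)), function(i) {
    adduct_mz(masses[[grid$name[i]]] + grid$isotopologue[i] * C13_SHIFT_EXACT,
              grid$adduct[i], convention)
  }, numeric(1))
  grid[order(grid$theoretical_mz), , drop = FALSE]
}

#' Annotate a vector of observed m/z values against a formula library
#'
#' Vectorised candidate matching: every (molecule, adduct, isotopologue)
#' combination whose theoretical m/z lies within `ppm_threshold` of an
#' observed value is reported. See [assign_candidates()] for the one-ion
#' interface.
#'
#' @param observed numeric vector of observed m/z values.
#' @param library formula library (data.frame with `name`, or character).
#' @param adducts adducts to consider.
#' @param ppm_threshold tolerance in ppm (default 10).
#' @param n_isotopologues isotopologue indices 0..n-1 (default 3).
#' @param convention see [adduct_mz()].
#' @return data.frame: observed, name, isotopologue, adduct,
#'   theoretical_mz, ppm; sorted by observed then `|ppm|`.
#' @export
annotate_peaks <- function(observed, library,
                           adducts = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+"),
                           ppm_threshold = 10, n_isotopologues = 3,
                           convention = "neutral") {
  tab <- library_mz_table(library, adducts, n_isotopologues, convention)
  t <- ppm_threshold * 1e-6
  out <- list()
  for (obs in observed) {
    i1 <- findInterval(obs / (1 + t), tab$theoretical_mz, left.open = TRUE) + 1L
    i2 <- findInterval(obs / (1 - t), tab$theoretical_mz)
    if (i2 >= i1) {
      hit <- tab[i1:i2, , drop = FALSE]
      hit$observed <- obs
      hit$ppm <- ppm_error(obs, hit$theoretical_mz)
      hit <- hit[abs(hit$ppm) <= ppm_threshold, , drop = FALSE]
      out[[length(out) + 1]] <- hit[order(abs(hit$ppm)), , drop = FALSE]
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(), adduct = character(),
                      isotopologue = integer(), theoretical_mz = numeric(),
                      observed = numeric(), ppm = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("observed", "name", "isotopologue", "adduct", "theoretical_mz",
          "ppm")]
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> average spectrum & peak picking -> ion
#' images -> screening -> PCA -> similarity clustering -> annotation,
#' writing every stage's outputs, a log and a machine-readable
#' `summary.json` into `out_dir`. Reruns with the same config and seed are
#' bit-identical (the summary records MD5 checksums of all outputs).
#'
#' @param config configuration list or YAML path; see [validate_config()].
#' @param seed integer seed governing all randomness.
#' @param out_dir output directory (created if needed).
#' @param formula_table formula library used for simulation and annotation.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = 42, out_dir,
                         formula_table = default_formula_library()) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  outputs <- character(0)
  keep <- function(path) { outputs <<- c(outputs, path); path }

  say("run: seed %d", seed)

  truth <- NULL
  if (cfg$simulate$enabled) {
    stage("simulate", {
      masks <- make_region_masks(cfg$simulate$width, cfg$simulate$height)
      truth <- make_ground_truth(
        cfg$simulate$n_molecules,
        archetype_weights = cfg$simulate$archetype_weights,
        formula_table = formula_table, seed = seed,
        raster = cfg$simulate$raster)
      noise <- noise_model(cfg$simulate$noise$baseline,
                           cfg$simulate$noise$spread,
                           cfg$simulate$noise$spurious_rate)
      dataset <- render_dataset(truth, masks, noise, seed = seed + 1L,
                                mz_range = cfg$mz_range,
                                n_isotopologues = cfg$simulate$n_isotopologues,
                                gradient = cfg$simulate$gradient)
      roi <- tissue_roi(masks)
      keep(write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv")))
      keep(write_roi_mask(roi, file.path(out_dir, "roi.tsv")))
      say("simulate: %d molecules on a %dx%d grid, %d spectra",
          nrow(truth$molecules), cfg$simulate$width, cfg$simulate$height,
          n_pixels(dataset))
    })
  } else {
    stage("load", {
      dataset <- read_imzml(cfg$input)
      roi <- NULL
      say("load: %d spectra from %s", n_pixels(dataset), cfg$input)
    })
  }

  avg <- NULL; peaks <- NULL
  stage("peaks", {
    avg <- average_spectrum(dataset, bin_width = cfg$peaks$bin_width)
    peaks <- pick_peaks(avg, snr_threshold = cfg$peaks$snr,
                         width = cfg$peaks$width)
    keep(write_tsv(data.frame(mz = peaks$mz, intensity = peaks$intensity,
                              snr = peaks$snr),
                   file.path(out_dir, "peaks.tsv")))
    say("peaks: %d picked from %d average-spectrum bins (noise %.4g)",
        length(peaks$mz), length(avg$mz), peaks$noise)
  })

  images <- NULL
  stage("images", {
    images <- ion_images(dataset, peaks, halfwidth = cfg$peaks$halfwidth)
    say("images: %d ion images extracted (halfwidth %g Da, maximum mode)",
        length(images), cfg$peaks$halfwidth)
  })

  kept <- images
  screen <- NULL
  if (cfg$screening$enabled && !is.null(roi)) {
    stage("screen", {
      screen <- screen_dataset(images, roi,
                                enrichment_threshold = cfg$screening$enrichment)
      kept <- screen$kept
      keep(write_tsv(as.data.frame(screen$report),
                     file.path(out_dir, "screen_report.tsv")))
      say("screen: kept %d of %d images (%d homogeneous, %d off-tissue discarded)",
          length(kept), length(images),
          sum(screen$report$label == "artefact_homogeneous"),
          sum(screen$report$label == "artefact_off_tissue"))
    })
  } else {
    say("screen: disabled; all %d images retained", length(images))
  }
  if (length(kept) < 2) stopf("pipeline stage 'screen' left fewer than 2 images")
  keep(export_ion_image_table(kept, file.path(out_dir, "ion_images.tsv")))

  pca <- NULL
  stage("pca", {
    pca <- run_pca(kept, n_components = cfg$pca$components)
    keep(write_tsv(
      data.frame(component = paste0("PC", seq_along(pca$contributions)),
                 contribution_pct = pca$contributions),
      file.path(out_dir, "pca_contributions.tsv")))
    say("pca: %d components, contributions %s",
        pca$parameters$n_components,
        paste(sprintf("%.1f%%", pca$contributions), collapse = " "))
  })

  groups <- NULL; occupancy <- NULL
  stage("cluster", {
    sim <- cosine_similarity_matrix(kept, roi = roi)
    ordering <- order_by_clustering(sim, linkage = cfg$cluster$linkage)
    groups <- extract_groups(sim, ordering,
                              threshold = cfg$cluster$threshold,
                              min_size = cfg$cluster$min_size)
    diag_groups <- Filter(function(g) g$kind == "diagonal", groups)
    occupancy <- occupancy_table(
      if (length(diag_groups)) diag_groups else numeric(0),
      total = length(kept))
    keep(write_tsv(as.data.frame(unclass(sim)),
                   file.path(out_dir, "similarity.tsv")))
    keep(write_tsv(do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(group = i, kind = groups[[i]]$kind,
                 members = paste(groups[[i]]$members, collapse = ","))
    })) %||% data.frame(group = integer(), kind = character(),
                        members = character()),
      file.path(out_dir, "groups.tsv")))
    keep(write_tsv(occupancy, file.path(out_dir, "occupancy.tsv")))
    say("cluster: %d diagonal and %d off-diagonal groups (threshold %g, min size %d)",
        length(diag_groups), length(groups) - length(diag_groups),
        cfg$cluster$threshold, cfg$cluster$min_size)
  })

  assignments <- NULL
  if (cfg$annotate$enabled) {
    stage("annotate", {
      centers <- vapply(kept, function(img) img$center, numeric(1))
      assignments <- annotate_peaks(
        centers, formula_table, adducts = cfg$annotate$adducts,
        ppm_threshold = cfg$annotate$ppm,
        n_isotopologues = cfg$annotate$n_isotopologues)
      keep(write_tsv(assignments, file.path(out_dir, "assignments.tsv")))
      say("annotate: %d candidate assignments for %d ions (<= %g ppm)",
          nrow(assignments), length(unique(assignments$observed)),
          cfg$annotate$ppm)
    })
  }

  checksums <- as.list(tools::md5sum(sort(outputs)))
  names(checksums) <- basename(sort(outputs))
  summary <- list(
    seed = seed,
    parameters = cfg,
    counts = list(
      pixels = n_pixels(dataset),
      picked_peaks = length(peaks$mz),
      images = length(images),
      kept = length(kept),
      discarded = length(images) - length(kept),
      diagonal_groups = sum(vapply(groups, function(g)
        g$kind == "diagonal", logical(1))),
      off_diagonal_groups = sum(vapply(groups, function(g)
        g$kind == "off_diagonal", logical(1))),
      assignments = if (is.null(assignments)) 0L else nrow(assignments)
    ),
    occupancy = occupancy,
    checksums = checksums
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: summary written")
  invisible(summary)
}
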