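# Independent oracles used across test files. These deliberately use naive
# algorithms (loops, exhaustive enumeration) so they share no code path with
# the implementation they check.

# Naive UPGMA on a similarity matrix: returns the cophenetic distance
# matrix built by repeated greedy merging of the closest cluster pair under
# average linkage on 1 - similarity.
naive_upgma_cophenetic <- function(sim) {
  n <- nrow(sim)
  d <- 1 - sim
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d - 1e-15) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    ia <- clusters[[best[1]]]
    ib <- clusters[[best[2]]]
    coph[ia, ib] <- best_d
    coph[ib, ia] <- best_d
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Exhaustive isotope-envelope enumeration for tiny molecules: every
# per-atom isotope assignment is enumerated and aggregated by nominal
# shift. Mirrors the definition, not the convolution.
enum_envelope <- function(composition, n_isotopologues = 3) {
  iso_tab <- list(
    C = cbind(shift = c(0, 1), mass = c(12, 13.0033548378),
              p = c(0.9893, 0.0107)),
    H = cbind(shift = c(0, 1), mass = c(1.00782503207, 2.01410177785),
              p = c(0.999885, 0.000115)),
    N = cbind(shift = c(0, 1), mass = c(14.0030740048, 15.0001088982),
              p = c(0.99636, 0.00364)),
    O = cbind(shift = c(0, 1, 2),
              mass = c(15.9949146196, 16.9991317012, 17.9991610),
              p = c(0.99757, 0.00038, 0.00205)),
    S = cbind(shift = c(0, 1, 2, 4),
              mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
              p = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  atoms <- list()
  for (el in names(composition)) {
    cnt <- composition[[el]]
    if (cnt > 0) atoms <- c(atoms, rep(list(iso_tab[[el]]), cnt))
  }
  stopifnot(length(atoms) <= 6)
  choices <- expand.grid(lapply(atoms, function(a) seq_len(nrow(a))))
  shift <- prob <- mass <- numeric(nrow(choices))
  for (r in seq_len(nrow(choices))) {
    s <- 0; p <- 1; m <- 0
    for (a in seq_along(atoms)) {
      row <- atoms[[a]][choices[r, a], ]
      s <- s + row[["shift"]]; p <- p * row[["p"]]; m <- m + row[["mass"]]
    }
    shift[r] <- s; prob[r] <- p; mass[r] <- m
  }
  agg_p <- tapply(prob, shift, sum)
  agg_m <- tapply(prob * mass, shift, sum) / agg_p
  ord <- order(as.numeric(names(agg_p)))
  keep <- ord[seq_len(min(n_isotopologues, length(ord)))]
  data.frame(
    shift = as.integer(names(agg_p)[keep]),
    mz_shift = as.numeric(agg_m[keep]) - as.numeric(agg_m[keep][1]),
    relative_intensity = as.numeric(agg_p[keep]) /
      as.numeric(agg_p[keep][1]) * 100
  )
}

# Brute-force average spectrum: accumulate bin sums with an explicit loop.
brute_average_spectrum <- function(dataset, bin_width = 0.001) {
  acc <- new.env()
  origin <- dataset$mz_range[1]
  for (s in dataset$spectra) {
    if (!length(s$mz)) next
    bins <- floor((s$mz - origin) / bin_width)
    for (i in seq_along(bins)) {
      key <- as.character(bins[i])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        s$intensity[i]
    }
  }
  keys <- as.numeric(ls(acc))
  keys <- sort(keys)
  data.frame(
    mz = origin + (keys + 0.5) * bin_width,
    intensity = vapply(as.character(keys), function(k) acc[[k]],
                       numeric(1)) / length(dataset$spectra)
  )
}

# Small deterministic phantom shared by I/O and peak tests.
small_phantom <- function(seed = 11, noise = noise_model(), width = 24,
                          height = 20, n_molecules = 12) {
  masks <- make_region_masks(width, height)
  species <- select_spaced_species(default_formula_library(), n_molecules,
                                   min_gap = 3)
  truth <- new_ground_truth(
    species,
    archetypes = rep(c("I", "III", "IV", "IX"),
                     length.out = n_molecules),
    adducts = "[M+H]+", base_intensity = 100, seed = seed)
  dataset <- render_dataset(truth, masks, noise, seed = seed)
  list(masks = masks, truth = truth, dataset = dataset,
       roi = tissue_roi(masks))
}
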