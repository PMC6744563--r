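# Glycerophospholipid annotation: shorthand parsing, monoisotopic and adduct
# masses, isotope envelopes, ppm matching and isotopologue-series detection.

# Monoisotopic atomic masses (Da), most abundant isotope of each element.
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668
)

# Natural isotope tables: nominal mass shift (vs lightest), exact mass (Da),
# abundance. Used by the full-mode envelope convolution.
ISOTOPE_TABLE <- list(
  C = data.frame(shift = c(0, 1),
                 mass = c(12, 13.0033548378),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(shift = c(0, 1),
                 mass = c(1.00782503207, 2.01410177785),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(shift = c(0, 1),
                 mass = c(14.0030740048, 15.0001088982),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(shift = c(0, 1, 2),
                 mass = c(15.9949146196, 16.9991317012, 17.9991610),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  P = data.frame(shift = 0, mass = 30.97376163, abundance = 1),
  S = data.frame(shift = c(0, 1, 2, 4),
                 mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = data.frame(shift = 0, mass = 22.9897692809, abundance = 1),
  K = data.frame(shift = c(0, 1, 2),
                 mass = c(38.96370668, 39.96399848, 40.96182576),
                 abundance = c(0.932581, 0.000117, 0.067302))
)

# 13C - 12C mass difference. The rounded 1.0034 Da value is the printed
# spacing of isotopologue series; the exact value is used for theoretical
# isotopologue masses.
C13_SHIFT_EXACT <- 13.0033548378 - 12
C13_SHIFT_DISPLAY <- 1.0034

ELECTRON_MASS <- 0.00054857990907

# Adduct compositions (the attached neutral atoms).
ADDUCT_COMPOSITIONS <- list(
  "[M+H]+"   = c(H = 1),
  "[M+NH4]+" = c(N = 1, H = 4),
  "[M+Na]+"  = c(Na = 1),
  "[M+K]+"   = c(K = 1)
)

# Diacyl glycerophospholipid head-group rules: element counts as a function
# of total acyl carbons c and double bonds d.
LIPID_CLASS_RULES <- list(
  PA = function(c, d) c(C = c + 3, H = 2 * c + 5 - 2 * d, O = 8, P = 1),
  PC = function(c, d) c(C = c + 8, H = 2 * c + 16 - 2 * d, N = 1, O = 8, P = 1),
  PE = function(c, d) c(C = c + 5, H = 2 * c + 10 - 2 * d, N = 1, O = 8, P = 1),
  PG = function(c, d) c(C = c + 6, H = 2 * c + 11 - 2 * d, O = 10, P = 1),
  PI = function(c, d) c(C = c + 9, H = 2 * c + 15 - 2 * d, O = 13, P = 1),
  PS = function(c, d) c(C = c + 6, H = 2 * c + 10 - 2 * d, N = 1, O = 10, P = 1)
)

#' Elemental composition from lipid shorthand
#'
#' Converts diacyl glycerophospholipid shorthand such as `"PS(39:0)"` into an
#' elemental composition (named integer vector of atom counts). Supported
#' classes: PA, PC, PE, PG, PI, PS, all as diacyl species with the total
#' number of acyl carbons and double bonds in parentheses.
#'
#' @param name lipid shorthand, `"<CLASS>(<carbons>:<doublebonds>)"`.
#' @return named integer vector of atom counts (class `composition`).
#' @examples
#' parse_lipid_shorthand("PS(39:0)")  # C45 H88 N O10 P
#' @export
parse_lipid_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regmatches(name, regexec("^([A-Za-z]+)\\((\\d+):(\\d+)\\)$", name))[[1]]
  if (length(m) != 4) {
    stopf("malformed lipid shorthand '%s'; expected '<CLASS>(<carbons>:<doublebonds>)'",
          name)
  }
  cls <- m[2]
  if (!cls %in% names(LIPID_CLASS_RULES)) {
    stopf("unknown lipid class '%s'; supported classes: %s",
          cls, paste(names(LIPID_CLASS_RULES), collapse = ", "))
  }
  carbons <- as.integer(m[3])
  db <- as.integer(m[4])
  comp <- LIPID_CLASS_RULES[[cls]](carbons, db)
  if (any(comp < 0)) stopf("invalid composition for '%s' (negative atom count)", name)
  structure(as.integer(comp), names = names(comp), class = "composition")
}

as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_lipid_shorthand(x))
  stopifnot(is.numeric(x), !is.null(names(x)))
  unknown <- setdiff(names(x), names(MONOISOTOPIC_MASS))
  if (length(unknown)) stopf("unsupported element(s): %s", paste(unknown, collapse = ", "))
  if (any(x < 0) || any(x != floor(x))) stopf("atom counts must be non-negative integers")
  structure(as.integer(x), names = names(x), class = "composition")
}

#' @export
format.composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition a `composition` (from [parse_lipid_shorthand()]), a
#'   named count vector, or a lipid shorthand string.
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("PS(39:0)")  # 833.6146
#' @export
monoisotopic_mass <- function(composition) {
  comp <- as_composition(composition)
  sum(comp * MONOISOTOPIC_MASS[names(comp)])
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Computes the m/z of a singly charged positive adduct. Two conventions are
#' supported: `"neutral"` adds the monoisotopic mass of the attached neutral
#' atoms (H, NH4, Na, K) with no electron correction — the convention under
#' which printed four-decimal adduct masses in FT-ICR lipid tables are
#' reproduced — and `"electron"` additionally subtracts one electron mass,
#' which is the physically exact m/z of the cation.
#'
#' @param mass neutral monoisotopic mass (Da), > 0.
#' @param adduct one of `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`, `"[M+K]+"`.
#' @param convention `"neutral"` (default) or `"electron"`.
#' @return adduct m/z in Da.
#' @examples
#' adduct_mz(833.6146, "[M+H]+")  # 834.6224
#' @export
adduct_mz <- function(mass, adduct, convention = c("neutral", "electron")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(mass), all(mass > 0))
  if (!adduct %in% names(ADDUCT_COMPOSITIONS)) {
    stopf("unknown adduct '%s'; supported: %s", adduct,
          paste(names(ADDUCT_COMPOSITIONS), collapse = ", "))
  }
  add <- ADDUCT_COMPOSITIONS[[adduct]]
  mz <- mass + sum(add * MONOISOTOPIC_MASS[names(add)])
  if (convention == "electron") mz <- mz - ELECTRON_MASS
  mz
}

#' Theoretical isotope envelope
#'
#' Computes the isotopologue envelope of a composition as (m/z shift,
#' relative intensity) pairs with the base (lightest) peak at 100.
#'
#' Two models are available. `"carbon"` is the carbon-only binomial
#' approximation: the k-th isotopologue carries `choose(nC, k) * r^k`
#' relative abundance with `r = 0.0107 / 0.9893` (the 13C/12C ratio), and
#' consecutive peaks are spaced 1.0034 Da apart — the model under which
#' FT-ICR phospholipid envelopes print as 100/49/12-style integer triples.
#' `"full"` convolves the complete natural-isotope tables of all elements
#' and aggregates to nominal-mass centroids (exact masses averaged with
#' abundance weights within each nominal shift).
#'
#' @param composition composition, named count vector, or shorthand string.
#' @param mode `"carbon"` (default) or `"full"`.
#' @param n_isotopologues number of isotopologues to return (>= 1).
#' @return data.frame with columns `shift` (integer nominal shift), `mz_shift`
#'   (Da above the monoisotopic mass) and `relative_intensity` (base = 100).
#' @examples
#' isotope_envelope("PS(39:0)", n_isotopologues = 3)
#' @export
isotope_envelope <- function(composition, mode = c("carbon", "full"),
                             n_isotopologues = 3) {
  mode <- match.arg(mode)
  comp <- as_composition(composition)
  stopifnot(n_isotopologues >= 1)
  if (sum(comp) < 1) stopf("composition must contain at least one atom")

  if (mode == "carbon") {
    n_c <- if ("C" %in% names(comp)) comp[["C"]] else 0L
    if (n_c == 0 && n_isotopologues > 1) {
      warning("composition has no carbon; carbon-only envelope is a single peak")
      return(data.frame(shift = 0L, mz_shift = 0,
                        relative_intensity = 100))
    }
    k <- seq_len(n_isotopologues) - 1L
    k <- k[k <= n_c]
    r <- 0.0107 / 0.9893
    rel <- choose(n_c, k) * r^k
    return(data.frame(
      shift = as.integer(k),
      mz_shift = k * C13_SHIFT_DISPLAY,
      relative_intensity = rel / rel[1] * 100
    ))
  }

  # full mode: elementwise convolution of (probability, mass-moment) vectors
  # over nominal shifts. M[k] accumulates sum(p * mass) so the centroid of
  # shift k is M[k] / P[k].
  p <- 1
  m <- 0
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    iso <- ISOTOPE_TABLE[[el]]
    for (i in seq_len(n)) {
      max_shift <- (length(p) - 1) + max(iso$shift)
      p_new <- numeric(max_shift + 1)
      m_new <- numeric(max_shift + 1)
      for (j in seq_len(nrow(iso))) {
        s <- iso$shift[j]; pj <- iso$abundance[j]; mj <- iso$mass[j]
        idx <- seq_along(p) + s
        p_new[idx] <- p_new[idx] + p * pj
        m_new[idx] <- m_new[idx] + m * pj + p * pj * mj
      }
      p <- p_new
      m <- m_new
    }
  }
  keep <- which(p > 0)[seq_len(min(n_isotopologues, sum(p > 0)))]
  centroid <- m[keep] / p[keep]
  data.frame(
    shift = as.integer(keep - 1L),
    mz_shift = centroid - centroid[1],
    relative_intensity = p[keep] / p[keep][1] * 100
  )
}

#' Parts-per-million mass error
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da), > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Detect isotopologue series in a peak list
#'
#' Greedy chaining of peaks spaced by the 13C isotopologue mass difference:
#' peak j extends a series ending at peak i when
#' `|mz_j - mz_i - delta| <= tol`. Maximal chains are returned; peaks that
#' chain to nothing are singleton series.
#'
#' @param mz ascending numeric vector of peak m/z values (or a `peakset`).
#' @param delta expected spacing in Da (default 1.0034).
#' @param tol matching tolerance in Da (> 0, default 0.01).
#' @return list of integer index vectors, one per series, in order of the
#'   series' first peak.
#' @export
detect_isotopologue_series <- function(mz, delta = C13_SHIFT_DISPLAY, tol = 0.01) {
  if (inherits(mz, "peakset")) mz <- mz$mz
  stopifnot(is.numeric(mz))
  if (tol <= 0) stopf("tol must be > 0")
  if (is.unsorted(mz)) stopf("peak m/z values must be ascending")
  n <- length(mz)
  series_of <- rep(NA_integer_, n)
  series <- list()
  for (i in seq_len(n)) {
    # extend the series whose tail is closest to mz[i] - delta
    cand <- which(!is.na(series_of) & abs(mz[i] - mz - delta) <= tol)
    cand <- cand[vapply(cand, function(j) {
      s <- series[[series_of[j]]]
      s[length(s)] == j
    }, logical(1))]
    if (length(cand)) {
      j <- cand[which.min(abs(mz[i] - mz[cand] - delta))]
      sid <- series_of[j]
      series[[sid]] <- c(series[[sid]], i)
      series_of[i] <- sid
    } else {
      series[[length(series) + 1]] <- i
      series_of[i] <- length(series)
    }
  }
  series
}

#' Candidate assignments for an observed m/z
#'
#' Matches an observed m/z against a formula library over a set of adducts
#' and isotopologue indices, keeping candidates within a ppm tolerance of
#' their theoretical m/z. Isotopologue theoretical masses use the exact 13C
#' shift (1.0033548 Da) added to the neutral monoisotopic mass. The ppm
#' threshold applies to every candidate individually; callers following the
#' accept-monoisotopic-then-propagate convention can filter on
#' `isotopologue == 0`.
#'
#' @param observed observed m/z (Da), length 1.
#' @param library formula library: data.frame with column `name` (lipid
#'   shorthand), or a character vector of shorthand names.
#' @param adducts adduct names to consider (default all four).
#' @param ppm_threshold tolerance in ppm (default 10).
#' @param n_isotopologues isotopologue indices 0..n-1 to consider (default 3).
#' @param convention adduct m/z convention, see [adduct_mz()].
#' @return data.frame (possibly empty) with columns `observed`, `name`,
#'   `isotopologue`, `adduct`, `theoretical_mz`, `ppm`, sorted by `|ppm|`.
#' @export
assign_candidates <- function(observed, library,
                              adducts = names(ADDUCT_COMPOSITIONS),
                              ppm_threshold = 10, n_isotopologues = 3,
                              convention = "neutral") {
  stopifnot(length(observed) == 1, is.numeric(observed))
  names_vec <- if (is.data.frame(library)) library$name else library
  if (length(names_vec) == 0) stopf("formula library is empty")
  out <- list()
  for (nm in names_vec) {
    mass <- monoisotopic_mass(nm)
    for (ad in adducts) {
      for (k in 0:(n_isotopologues - 1)) {
        theo <- adduct_mz(mass + k * C13_SHIFT_EXACT, ad, convention)
        ppm <- ppm_error(observed, theo)
        if (abs(ppm) <= ppm_threshold) {
          out[[length(out) + 1]] <- data.frame(
            observed = observed, name = nm, isotopologue = k,
            adduct = ad, theoretical_mz = theo, ppm = ppm,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(observed = numeric(), name = character(),
                      isotopologue = integer(), adduct = character(),
                      theoretical_mz = numeric(), ppm = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(abs(res$ppm)), , drop = FALSE]
}

#' Score an observed isotopologue series against a theoretical envelope
#'
#' Cosine similarity between the observed relative-intensity vector and the
#' theoretical envelope intensities, truncated to the common length.
#'
#' @param observed observed intensities (base peak first).
#' @param envelope an envelope data.frame from [isotope_envelope()] or a
#'   numeric intensity vector.
#' @return cosine similarity in [0, 1].
#' @export
match_envelope <- function(observed, envelope) {
  theo <- if (is.data.frame(envelope)) envelope$relative_intensity else envelope
  stopifnot(length(observed) >= 1, length(theo) >= 1)
  n <- min(length(observed), length(theo))
  obs <- observed[seq_len(n)]
  theo <- theo[seq_len(n)]
  if (all(obs == 0)) stopf("observed intensity vector is all zero")
  sum(obs * theo) / sqrt(sum(obs^2) * sum(theo^2))
}

#' Full assignment table for a set of observed ions
#'
#' End-to-end regeneration of a printed assignment table: for each observed
#' m/z with a designated (molecule, adduct, isotopologue) assignment, compute
#' the theoretical neutral mass (monoisotopic + k exact 13C shifts), the
#' adduct m/z, and the ppm delta. Theoretical values are rounded half away
#' from zero to 4 decimals before the ppm division, matching the arithmetic
#' of printed four-decimal tables, and the ppm is reported to 2 decimals.
#'
#' @param assignments data.frame with columns `observed` (m/z), `name`
#'   (lipid shorthand), `adduct`, `isotopologue` (0-based integer).
#' @param convention adduct convention, see [adduct_mz()].
#' @return the input with added columns `theoretical_mass`, `adduct_mz`
#'   (both rounded to 4 decimals) and `delta_ppm` (2 decimals).
#' @export
assignment_table <- function(assignments, convention = "neutral") {
  stopifnot(all(c("observed", "name", "adduct", "isotopologue") %in%
                  names(assignments)))
  n <- nrow(assignments)
  theo_mass <- numeric(n)
  theo_mz <- numeric(n)
  for (i in seq_len(n)) {
    mono <- monoisotopic_mass(assignments$name[i])
    mass <- mono + assignments$isotopologue[i] * C13_SHIFT_EXACT
    theo_mass[i] <- mass
    theo_mz[i] <- adduct_mz(mass, assignments$adduct[i], convention)
  }
  out <- assignments
  out$theoretical_mass <- round_half_up(theo_mass, 4)
  out$adduct_mz <- round_half_up(theo_mz, 4)
  out$delta_ppm <- round_half_up(
    ppm_error(assignments$observed, round_half_up(theo_mz, 4)), 2)
  out
}

#' Read a formula library from TSV
#'
#' Expects columns `name`, `class`, `carbons`, `double_bonds`; extra columns
#' are preserved.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_formula_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "carbons", "double_bonds")
  if (!all(need %in% names(tab))) {
    stopf("formula library must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0) stopf("formula library is empty")
  tab
}

#' Bundled glycerophospholipid library
#'
#' The package ships a small diacyl glycerophospholipid table (PA, PC, PE,
#' PG, PI, PS species) whose common positive adducts fall in m/z 700-900;
#' it stands in for an external metabolome database in examples, phantom
#' generation and tests.
#'
#' @return data.frame with columns name, class, carbons, double_bonds.
#' @export
default_formula_library <- function() {
  read_formula_library(
    system.file("extdata", "glycerophospholipids.tsv", package = "msiclust",
                mustWork = TRUE))
}
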