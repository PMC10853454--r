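# Monoisotopic residue masses (Da); proton and water per standard references.
MONO_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
PROTON_MASS <- 1.007276
WATER_MASS  <- 18.010565

residue_masses <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% names(MONO_MASS))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  MONO_MASS[aa]
}

#' Monoisotopic neutral mass of a peptide
#' @param peptide Peptide string (standard residues).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(peptide) sum(residue_masses(peptide)) + WATER_MASS

#' Theoretical b/y fragment ions of a peptide
#'
#' Generates all `b_i` and `y_i` ions for `i` in `[1, n - 1]` at charges
#' `1..max_charge`. Neutral fragment masses are `b = sum(residues)` and
#' `y = sum(residues) + water`; m/z is `(neutral + z * proton) / z`. Only the
#' b/y series are produced (HCD backbone ions); no neutral losses.
#'
#' @param peptide Peptide string.
#' @param max_charge Maximum fragment charge (>= 1).
#' @return Data frame with columns `series`, `index`, `charge`, `label`
#'   (e.g. `"y3"`), `mz`.
#' @export
theoretical_fragments <- function(peptide, max_charge = 2L) {
  stopifnot(max_charge >= 1L)
  rm_ <- residue_masses(peptide)
  n <- length(rm_)
  if (n < 2L) stop("peptide must have at least 2 residues")
  idx <- seq_len(n - 1L)
  b_neutral <- cumsum(rm_)[idx]
  y_neutral <- cumsum(rev(rm_))[idx] + WATER_MASS
  grid <- expand.grid(index = idx, charge = seq_len(max_charge),
                      series = c("b", "y"), stringsAsFactors = FALSE)
  neutral <- ifelse(grid$series == "b", b_neutral[grid$index],
                    y_neutral[grid$index])
  data.frame(series = grid$series, index = grid$index, charge = grid$charge,
             label = paste0(grid$series, grid$index),
             mz = (neutral + grid$charge * PROTON_MASS) / grid$charge)
}

#' Construct a spectrum
#'
#' Peaks are stored sorted by m/z; matching results are therefore invariant
#' to the input peak order.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0), same length.
#' @param precursor_charge Precursor charge (>= 1).
#' @param peptide Optional peptide annotation.
#' @param label Spectrum identifier.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, precursor_charge = 2L, peptide = NA_character_,
                     label = "spectrum") {
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0),
            precursor_charge >= 1L)
  ord <- order(mz)
  structure(list(peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
                 precursor_charge = as.integer(precursor_charge),
                 peptide = peptide, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d peaks, precursor z=%d%s\n", x$label,
              nrow(x$peaks), x$precursor_charge,
              if (is.na(x$peptide)) "" else paste0(", peptide ", x$peptide)))
  invisible(x)
}

#' Match theoretical ions against a spectrum's peaks
#'
#' Greedy closest-wins assignment: among all (ion, peak) pairs within the
#' tolerance, the smallest m/z difference is assigned first and both partners
#' are retired; ties on the difference are broken towards the lower peak m/z.
#' Each peak serves at most one ion; unmatched ions carry intensity 0.
#'
#' @param spec A `spectrum`.
#' @param ions Data frame from [theoretical_fragments()].
#' @param tolerance Numeric tolerance value.
#' @param unit `"ppm"` or `"Da"`.
#' @return `ions` with extra columns `matched_intensity` and `matched_mz`
#'   (`NA` when unmatched).
#' @export
match_peaks <- function(spec, ions, tolerance = 20, unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  stopifnot(tolerance > 0)
  peaks <- spec$peaks
  ions$matched_intensity <- 0
  ions$matched_mz <- NA_real_
  if (nrow(peaks) == 0L || nrow(ions) == 0L) return(ions)

  tol_abs <- function(mz) if (unit == "ppm") mz * tolerance * 1e-6 else tolerance
  cand <- list()
  for (i in seq_len(nrow(ions))) {
    d <- abs(peaks$mz - ions$mz[i])
    ok <- which(d <= tol_abs(ions$mz[i]))
    if (length(ok)) {
      cand[[length(cand) + 1L]] <-
        data.frame(ion = i, peak = ok, delta = d[ok], peak_mz = peaks$mz[ok])
    }
  }
  if (!length(cand)) return(ions)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$delta, cand$peak_mz), , drop = FALSE]
  used_ion <- logical(nrow(ions)); used_peak <- logical(nrow(peaks))
  for (r in seq_len(nrow(cand))) {
    i <- cand$ion[r]; p <- cand$peak[r]
    if (used_ion[i] || used_peak[p]) next
    used_ion[i] <- TRUE; used_peak[p] <- TRUE
    ions$matched_intensity[i] <- peaks$intensity[p]
    ions$matched_mz[i] <- peaks$mz[p]
  }
  ions
}

#' Charge-deconvolute per-ion matched intensities
#'
#' Intensities of the same fragment label observed at different charge states
#' are summed into one per-label value; the total intensity is conserved.
#'
#' @param matched_ions Data frame from [match_peaks()] (columns `label`,
#'   `series`, `index`, `charge`, `matched_intensity`).
#' @return Data frame with one row per label: `label`, `series`, `index`,
#'   `mz1` (z = 1 m/z), `intensity`.
#' @export
charge_deconvolute <- function(matched_ions) {
  stopifnot(all(matched_ions$matched_intensity >= 0))
  split_ <- split(matched_ions, matched_ions$label)
  out <- lapply(split_, function(g) {
    z1 <- g$mz[g$charge == 1L]
    data.frame(label = g$label[1], series = g$series[1], index = g$index[1],
               mz1 = if (length(z1)) z1[1] else g$mz[1] * g$charge[1] -
                 (g$charge[1] - 1) * PROTON_MASS,
               intensity = sum(g$matched_intensity), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$series, out$index), , drop = FALSE]
}

#' Match an acquired and a predicted spectrum on shared fragment labels
#'
#' Both spectra are matched per charge state against the same theoretical
#' b/y ions, charge-deconvoluted symmetrically, and reduced to the fragment
#' labels with positive matched intensity in *both* spectra -- the matched
#' fragment set the spectrum contrast angle is computed from.
#'
#' @param acquired,predicted `spectrum` objects.
#' @param peptide Peptide sequence generating the theoretical ions.
#' @param max_charge Maximum fragment charge considered.
#' @param tolerance,unit Matching tolerance (see [match_peaks()]).
#' @return Object of class `matched_fragments`: data frame with `label`,
#'   `series`, `index`, `mz1`, `acquired`, `predicted`; attribute
#'   `tolerance`.
#' @export
match_fragment_sets <- function(acquired, predicted, peptide, max_charge = 2L,
                                tolerance = 20, unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  ions <- theoretical_fragments(peptide, max_charge)
  a <- charge_deconvolute(match_peaks(acquired, ions, tolerance, unit))
  p <- charge_deconvolute(match_peaks(predicted, ions, tolerance, unit))
  stopifnot(identical(a$label, p$label))
  keep <- a$intensity > 0 & p$intensity > 0
  out <- data.frame(label = a$label[keep], series = a$series[keep],
                    index = a$index[keep], mz1 = a$mz1[keep],
                    acquired = a$intensity[keep], predicted = p$intensity[keep],
                    stringsAsFactors = FALSE)
  attr(out, "tolerance") <- c(value = tolerance)
  attr(out, "tolerance_unit") <- unit
  class(out) <- c("matched_fragments", "data.frame")
  out
}
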