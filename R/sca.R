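#' Spectrum contrast angle between two intensity vectors
#'
#' The angle theta between two non-negative intensity vectors is mapped to
#' `1 - 2 * theta / pi`, so that identical (parallel) spectra score 1 and
#' spectra with disjoint fragment support (orthogonal vectors) score 0. The
#' score is symmetric and invariant to positive rescaling of either vector,
#' so no intensity normalisation is applied beforehand.
#'
#' @param a,b Non-negative numeric vectors of equal length (>= 1), each with
#'   at least one positive entry.
#' @return Similarity in `[0, 1]`.
#' @export
spectrum_contrast_angle <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  if (any(a < 0) || any(b < 0)) stop("intensities must be non-negative")
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0) stop("all-zero intensity vector: angle undefined")
  dot <- sum(a * b)
  # parallel vectors (identical spectra up to scale) have angle exactly 0;
  # comparing dot^2 against the squared-norm product avoids the acos
  # round-off that would otherwise leave SCA(a, a) a hair below 1
  if (dot * dot >= sa * sb) return(1)
  1 - 2 * acos(dot / sqrt(sa * sb)) / pi
}

#' Restrict a matched fragment set to the top-k predicted intensities
#'
#' Ranking is by predicted intensity descending; ties are broken towards the
#' lower singly-charged m/z. When fewer than `k` labels are matched, all are
#' kept and the realised count is recorded.
#'
#' @param matched A `matched_fragments` object (see [match_fragment_sets()]).
#' @param k Number of fragments to retain (>= 1).
#' @return The restricted `matched_fragments`, with attribute `k_used`.
#' @export
select_top_k <- function(matched, k = 8L) {
  stopifnot(k >= 1L)
  if (nrow(matched) == 0L) {
    stop("no overlapping matched fragments between the two spectra")
  }
  ord <- order(-matched$predicted, matched$mz1)
  keep <- sort(ord[seq_len(min(k, nrow(matched)))])
  out <- matched[keep, , drop = FALSE]
  attr(out, "k_used") <- length(keep)
  attr(out, "tolerance") <- attr(matched, "tolerance")
  class(out) <- class(matched)
  out
}

#' Bootstrap stability of the spectrum contrast angle
#'
#' The point estimate is the SCA of the acquired vs predicted intensities
#' over the top-`k` matched fragment pairs. Stability is assessed by
#' resampling those fragment *pairs* with replacement `n_boot` times and
#' recomputing the SCA on each resample; a degenerate resample (an all-zero
#' vector) is redrawn, with a capped retry count.
#'
#' @param matched A `matched_fragments` object.
#' @param k Top-k fragments by predicted intensity (default 8).
#' @param n_boot Number of bootstrap resamples (default 20).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param max_retries Retry cap per degenerate replicate.
#' @return Object of class `sca_result`: list with `sca`, `k_used`,
#'   `bootstrap_values`, `n_boot`, `seed`, `median`, `q1`, `q3`.
#' @export
bootstrap_sca <- function(matched, k = 8L, n_boot = 20L, seed,
                          max_retries = 100L) {
  stopifnot(k >= 2L, n_boot >= 1L)
  if (missing(seed)) stop("seed is required")
  top <- select_top_k(matched, k)
  point <- spectrum_contrast_angle(top$acquired, top$predicted)
  m <- nrow(top)
  values <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(m, m, replace = TRUE)
        a <- top$acquired[idx]; p <- top$predicted[idx]
        if (sum(a) > 0 && sum(p) > 0) return(spectrum_contrast_angle(a, p))
      }
      stop("bootstrap replicate degenerate after ", max_retries, " retries")
    }, numeric(1))
  })
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(sca = point, k_used = attr(top, "k_used"),
                 bootstrap_values = values, n_boot = as.integer(n_boot),
                 seed = as.integer(seed),
                 q1 = qs[1], median = qs[2], q3 = qs[3]),
            class = "sca_result")
}

#' @export
print.sca_result <- function(x, ...) {
  cat(sprintf("<sca_result> SCA = %.4f (k = %d), bootstrap n = %d: median %.4f [Q1 %.4f, Q3 %.4f]\n",
              x$sca, x$k_used, x$n_boot, x$median, x$q1, x$q3))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
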