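#' Filter a DIA-style report table
#'
#' Keeps rows passing all four predicates, exactly as printed search-report
#' conventions define them: precursor `q_value <= 0.01`, `protein_q_value <=
#' 0.01`, `mass_evidence > 0.5`, `precursor_charge > 1`. Row order is
#' preserved.
#'
#' @param records Data frame with columns `q_value`, `protein_q_value`,
#'   `mass_evidence`, `precursor_charge`.
#' @param q_cut,protein_q_cut,mass_evidence_cut,min_charge Threshold
#'   overrides.
#' @return The filtered data frame.
#' @export
filter_report <- function(records, q_cut = 0.01, protein_q_cut = 0.01,
                          mass_evidence_cut = 0.5, min_charge = 1) {
  required <- c("q_value", "protein_q_value", "mass_evidence", "precursor_charge")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("report is missing required column(s): ", paste(missing, collapse = ", "))
  }
  keep <- records$q_value <= q_cut &
    records$protein_q_value <= protein_q_cut &
    records$mass_evidence > mass_evidence_cut &
    records$precursor_charge > min_charge
  records[keep, , drop = FALSE]
}

#' Impute missing log2 intensities from a down-shifted normal
#'
#' Missing-not-at-random holes in label-free data sit preferentially at low
#' abundance, so each missing cell is drawn from a normal distribution
#' narrowed to `width_factor` times the observed SD and down-shifted by
#' `shift_sd` observed SDs below the observed mean. By default the observed
#' mean/SD are computed per sample column (the Perseus convention); set
#' `per_column = FALSE` for a single global distribution.
#'
#' @param matrix Numeric matrix of log2 intensities with `NA` for missing.
#' @param width_factor SD shrink factor for the imputation distribution
#'   (default 0.25).
#' @param shift_sd Down-shift in observed-SD units (default 1.8).
#' @param seed Integer seed (required).
#' @param per_column Compute mean/SD per column (default) or globally.
#' @return List with `matrix` (completed), `imputed` (logical mask of cells
#'   that were filled in).
#' @export
impute_missing <- function(matrix, width_factor = 0.25, shift_sd = 1.8, seed,
                           per_column = TRUE) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (sum(!is.na(matrix)) < 2L) stop("need at least 2 observed values")
  mask <- is.na(matrix)
  out <- matrix
  local_seed(seed, {
    if (per_column) {
      for (j in seq_len(ncol(out))) {
        nm <- sum(mask[, j])
        if (nm == 0L) next
        obs <- out[!mask[, j], j]
        if (length(obs) < 2L) stop(sprintf(
          "column %d has fewer than 2 observed values; use per_column = FALSE", j))
        mu <- mean(obs); s <- stats::sd(obs)
        out[mask[, j], j] <- stats::rnorm(nm, mu - shift_sd * s, width_factor * s)
      }
    } else {
      obs <- out[!mask]
      mu <- mean(obs); s <- stats::sd(obs)
      out[mask] <- stats::rnorm(sum(mask), mu - shift_sd * s, width_factor * s)
    }
  })
  list(matrix = out, imputed = mask)
}

#' Per-protein two-group differential test
#'
#' Row-wise two-sample t test (Welch by default) with Benjamini-Hochberg
#' adjustment across proteins. The log2 fold change is `mean(group A) -
#' mean(group B)` on the log2 scale. Rows with zero variance in both groups
#' and equal means get `p = 1` by convention and are flagged `degenerate`.
#'
#' @param matrix Completed numeric matrix (proteins x samples), log2 scale.
#' @param groups Character/factor vector of length `ncol(matrix)` with
#'   exactly two levels; the first level encountered is "group A".
#' @param var_equal Use the pooled-variance Student t test instead of Welch.
#' @return Data frame: `protein`, `log2fc`, `p_value`, `adjusted_p`,
#'   `degenerate`.
#' @export
differential_test <- function(matrix, groups, var_equal = FALSE) {
  stopifnot(is.matrix(matrix), length(groups) == ncol(matrix))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups are required")
  ia <- groups == lv[1]; ib <- groups == lv[2]
  if (sum(ia) < 2L || sum(ib) < 2L) stop("each group needs >= 2 samples")

  n <- nrow(matrix)
  p <- numeric(n); fc <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    a <- matrix[i, ia]; b <- matrix[i, ib]
    fc[i] <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degen[i] <- TRUE
      p[i] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p[i] <- stats::t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("protein_", seq_len(n))
  data.frame(protein = ids, log2fc = fc, p_value = p,
             adjusted_p = stats::p.adjust(p, method = "BH"),
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Classify differential results for a volcano plot
#'
#' A protein is called up in group A when `log2fc >= lfc_cut` and the
#' adjusted p-value is below `p_cut`; up in group B when `log2fc <=
#' -lfc_cut` under the same p cut; otherwise not significant. The default
#' `p_cut = 0.5` reproduces the printed analysis cut-off exactly; note this
#' is an order of magnitude more permissive than the conventional 0.05 and
#' is deliberately exposed as a parameter.
#'
#' @param results Data frame from [differential_test()].
#' @param lfc_cut Absolute log2 fold-change cut (default 2).
#' @param p_cut Adjusted p-value cut (default 0.5, as printed).
#' @return `results` with a `class` column in
#'   `{up_A, up_B, not_significant}`.
#' @export
classify_volcano <- function(results, lfc_cut = 2, p_cut = 0.5) {
  cls <- rep("not_significant", nrow(results))
  cls[results$log2fc >= lfc_cut & results$adjusted_p < p_cut] <- "up_A"
  cls[results$log2fc <= -lfc_cut & results$adjusted_p < p_cut] <- "up_B"
  results$class <- cls
  results
}

#' Z-scored median intensity profiles
#'
#' Per protein: the median over replicate columns within each condition,
#' then a row z-score across conditions (population-SD convention by
#' default). Constant rows are mapped to all zeros and flagged.
#'
#' @param matrix Numeric matrix (proteins x samples).
#' @param replicate_groups Condition label per column.
#' @param population_sd Divide by the population SD (default) or sample SD.
#' @return List with `profiles` (proteins x conditions matrix) and
#'   `constant` (logical per protein).
#' @export
zscore_profiles <- function(matrix, replicate_groups, population_sd = TRUE) {
  stopifnot(is.matrix(matrix), length(replicate_groups) == ncol(matrix))
  conds <- unique(as.character(replicate_groups))
  med <- sapply(conds, function(cc) {
    apply(matrix[, replicate_groups == cc, drop = FALSE], 1, stats::median)
  })
  med <- matrix(med, nrow = nrow(matrix), dimnames = list(rownames(matrix), conds))
  mu <- rowMeans(med)
  dev <- med - mu
  s <- if (population_sd) sqrt(rowMeans(dev^2)) else apply(med, 1, stats::sd)
  constant <- s == 0
  z <- dev / ifelse(constant, 1, s)
  z[constant, ] <- 0
  list(profiles = z, constant = constant)
}
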