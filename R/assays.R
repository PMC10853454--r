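#' Shedding ratio from a fluorescence plate
#'
#' For each condition the ratio of mean background-corrected supernatant
#' fluorescence to mean background-corrected cell fluorescence is computed
#' (`Ratio = F_supernatant / F_cell`), then normalised by the control
#' condition's ratio so the control is exactly 1. Background-corrected
#' supernatant means that fall below zero are clipped to 0; a non-positive
#' corrected cell mean leaves the ratio undefined and is an error.
#'
#' @param plate Data frame with columns `condition`, `compartment`
#'   (`"supernatant"` or `"cell"`), `fluorescence`.
#' @param control_condition Label of the control condition.
#' @param background Named numeric `c(supernatant = ..., cell = ...)` from
#'   blank wells / pure medium.
#' @return Data frame: `condition`, `ratio`, `normalized_ratio` (control = 1).
#' @export
shedding_ratio <- function(plate, control_condition,
                           background = c(supernatant = 0, cell = 0)) {
  stopifnot(all(c("condition", "compartment", "fluorescence") %in% names(plate)),
            all(plate$compartment %in% c("supernatant", "cell")),
            all(plate$fluorescence >= 0))
  if (!control_condition %in% plate$condition) {
    stop("control condition '", control_condition, "' not present on plate")
  }
  conds <- unique(plate$condition)
  ratio <- vapply(conds, function(cc) {
    sup <- plate$fluorescence[plate$condition == cc &
                              plate$compartment == "supernatant"]
    cel <- plate$fluorescence[plate$condition == cc & plate$compartment == "cell"]
    if (!length(sup) || !length(cel)) {
      stop("condition '", cc, "' needs wells in both compartments")
    }
    sup_c <- max(0, mean(sup) - background[["supernatant"]])
    cel_c <- mean(cel) - background[["cell"]]
    if (cel_c <= 0) stop("corrected cell fluorescence <= 0 for '", cc,
                         "': ratio undefined")
    sup_c / cel_c
  }, numeric(1))
  data.frame(condition = conds, ratio = unname(ratio),
             normalized_ratio = unname(ratio / ratio[conds == control_condition]),
             stringsAsFactors = FALSE)
}

#' Normalise a FRET trace to a 0-100% cAMP response scale
#'
#' Both channels are background-subtracted, the acceptor is corrected for
#' donor bleed-through (`acceptor - bleed_through * donor`), and the
#' donor/acceptor ratio is affine-mapped so that the mean of the
#' `baseline_n` points immediately before ligand addition is 0% and the mean
#' of the final `plateau_n` points after the saturating stimulus
#' (Forskolin/IBMX-style maximal response) is 100%.
#'
#' @param trace Data frame with columns `time`, `donor`, `acceptor`.
#' @param ligand_index Index of the first point after ligand addition.
#' @param stimulus_index Index of the first point after the saturating
#'   stimulus.
#' @param bleed_through Donor-into-acceptor bleed-through fraction in
#'   `[0, 1)`, measured from donor-only controls.
#' @param background Named numeric `c(donor = ..., acceptor = ...)`.
#' @param baseline_n Baseline points before ligand addition (default 10).
#' @param plateau_n Plateau points at the trace end (default 10).
#' @return `trace` with columns `ratio` (corrected donor/acceptor) and
#'   `response` (percent of maximal).
#' @export
fret_normalize <- function(trace, ligand_index, stimulus_index,
                           bleed_through = 0, background = c(donor = 0, acceptor = 0),
                           baseline_n = 10L, plateau_n = 10L) {
  stopifnot(all(c("time", "donor", "acceptor") %in% names(trace)),
            bleed_through >= 0, bleed_through < 1)
  n <- nrow(trace)
  if (ligand_index <= baseline_n) {
    stop("need at least ", baseline_n, " baseline points before ligand addition")
  }
  if (stimulus_index <= ligand_index || stimulus_index > n - 1L) {
    stop("saturating stimulus must fall after ligand addition and before trace end")
  }
  donor_c <- trace$donor - background[["donor"]]
  acceptor_c <- trace$acceptor - background[["acceptor"]] - bleed_through * donor_c
  if (any(acceptor_c <= 0)) stop("corrected acceptor channel non-positive")
  ratio <- donor_c / acceptor_c
  baseline <- mean(ratio[(ligand_index - baseline_n):(ligand_index - 1L)])
  plateau <- mean(ratio[(n - plateau_n + 1L):n])
  if (plateau <= baseline) stop("plateau does not exceed baseline: normalisation degenerate")
  trace$ratio <- ratio
  trace$response <- (ratio - baseline) / (plateau - baseline) * 100
  trace
}

#' Three-parameter concentration-response fit
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + 10^(logEC50 - log10(conc)))`, the standard three-parameter logistic
#' with Hill slope fixed at 1. Initialisation is a deterministic multi-start
#' over data quantiles (response range for bottom/top, concentration
#' quantiles for logEC50); the best converged start wins. Optionally the
#' bottom can be fixed at 0.
#'
#' @param concentration Molar concentrations (> 0), >= 4 distinct values.
#' @param response Responses, same length.
#' @param fix_bottom Fix the bottom asymptote at this value (e.g. 0);
#'   `NULL` (default) estimates it.
#' @return Object of class `dose_response_fit`: list with `bottom`, `top`,
#'   `logEC50`, `residual_ss`, `df`, `n`, `converged`, `fitted` (function of
#'   concentration), `coefficients`.
#' @export
fit_dose_response <- function(concentration, response, fix_bottom = NULL) {
  stopifnot(length(concentration) == length(response), all(concentration > 0))
  if (length(unique(concentration)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  lx <- log10(concentration)
  if (stats::sd(response) == 0) {
    # flat data: the model is unidentifiable in logEC50
    npar <- if (is.null(fix_bottom)) 3L else 2L
    fit <- list(bottom = if (is.null(fix_bottom)) response[1] else fix_bottom,
                top = response[1], logEC50 = stats::median(lx),
                residual_ss = 0, df = length(response) - npar,
                n = length(response), converged = FALSE, degenerate = TRUE)
    fit$fitted <- local({
      b <- fit$bottom; t_ <- fit$top; le <- fit$logEC50
      function(conc) b + (t_ - b) / (1 + 10^(le - log10(conc)))
    })
    class(fit) <- "dose_response_fit"
    return(fit)
  }

  model3 <- function(p, x) p[1] + (p[2] - p[1]) / (1 + 10^(p[3] - x))
  rng <- range(response)
  starts_le <- stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list()
  for (le in starts_le) {
    starts[[length(starts) + 1L]] <- c(rng[1], rng[2], le)
    starts[[length(starts) + 1L]] <- c(rng[2], rng[1], le)
  }
  best <- NULL
  for (st in starts) {
    res_fn <- if (is.null(fix_bottom)) {
      function(p) response - model3(p, lx)
    } else {
      function(p) response - model3(c(fix_bottom, p), lx)
    }
    p0 <- if (is.null(fix_bottom)) st else st[2:3]
    out <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) next
    ss <- sum(out$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(ss = ss, fit = out)
  }
  if (is.null(best)) stop("dose-response fit failed to converge from any start")
  p <- best$fit$par
  if (!is.null(fix_bottom)) p <- c(fix_bottom, p)
  npar <- if (is.null(fix_bottom)) 3L else 2L
  fit <- list(bottom = p[1], top = p[2], logEC50 = p[3],
              residual_ss = best$ss, df = length(response) - npar,
              n = length(response),
              converged = best$fit$info %in% 1:4, degenerate = FALSE)
  fit$fitted <- local({
    b <- p[1]; t_ <- p[2]; le <- p[3]
    function(conc) b + (t_ - b) / (1 + 10^(le - log10(conc)))
  })
  class(fit) <- "dose_response_fit"
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> bottom %.4g, top %.4g, logEC50 %.4g (SS %.4g, df %d)\n",
              x$bottom, x$top, x$logEC50, x$residual_ss, x$df))
  invisible(x)
}

#' Extra-sum-of-squares F test between nested fits
#'
#' Compares a constrained (shared-parameter) fit against a richer
#' (separate-parameter) fit of the same data: `F = ((SS_shared - SS_sep) /
#' (df_shared - df_sep)) / (SS_sep / df_sep)`, with the p-value from the
#' upper tail of the F distribution. Used e.g. to ask whether two
#' concentration-response curves need different tops.
#'
#' @param shared_fit,separate_fit Objects with `residual_ss` and `df`
#'   elements ([fit_dose_response()] results, or plain lists for pooled
#'   multi-curve fits). `separate_fit` must be the richer model.
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
ess_f_test <- function(shared_fit, separate_fit) {
  ss0 <- shared_fit$residual_ss; df0 <- shared_fit$df
  ss1 <- separate_fit$residual_ss; df1_ <- separate_fit$df
  if (df0 <= df1_) stop("shared model must have more residual df than the separate model")
  if (ss1 == 0) {
    warning("separate-model residual SS is exactly 0; p set to 0 by convention")
    return(list(F = Inf, df1 = df0 - df1_, df2 = df1_, p = 0))
  }
  Fv <- max(0, (ss0 - ss1) / (df0 - df1_)) / (ss1 / df1_)
  list(F = Fv, df1 = df0 - df1_, df2 = df1_,
       p = stats::pf(Fv, df0 - df1_, df1_, lower.tail = FALSE))
}

#' Compare two concentration-response curves
#'
#' Fits the two datasets jointly under a shared three-parameter curve and
#' separately with per-curve parameters, then runs the extra-sum-of-squares
#' F test on the nested pair.
#'
#' @param conc1,resp1,conc2,resp2 The two datasets.
#' @return List with `shared`, `fit1`, `fit2`, and `test` (the
#'   [ess_f_test()] result).
#' @export
compare_dose_response <- function(conc1, resp1, conc2, resp2) {
  f1 <- fit_dose_response(conc1, resp1)
  f2 <- fit_dose_response(conc2, resp2)
  shared <- fit_dose_response(c(conc1, conc2), c(resp1, resp2))
  sep <- list(residual_ss = f1$residual_ss + f2$residual_ss,
              df = f1$df + f2$df)
  list(shared = shared, fit1 = f1, fit2 = f2,
       test = ess_f_test(shared, sep))
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = (10^(-1/slope) - 1) * 100`, in percent; a slope of
#' `-1/log10(2) = -3.3219` corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope (Ct vs log10 template), non-zero.
#' @return Efficiency in percent.
#' @export
qpcr_efficiency <- function(slope) {
  stopifnot(is.numeric(slope))
  if (any(slope == 0)) stop("slope must be non-zero")
  (10^(-1 / slope) - 1) * 100
}
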