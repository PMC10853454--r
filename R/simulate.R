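#' Generate a random protein sequence
#'
#' Residues are drawn uniformly from the 20-letter alphabet; a given seed
#' always yields the same record.
#'
#' @param length Number of residues (>= 10).
#' @param seed Integer seed.
#' @param id Identifier for the record.
#' @return A `protein_record`.
#' @export
generate_protein <- function(length, seed, id = "sim_protein") {
  stopifnot(length >= 10L)
  seq <- local_seed(seed, paste(sample(AA_LETTERS, length, replace = TRUE),
                                collapse = ""))
  protein_record(id, seq, description = "simulated")
}

#' Simulate peptide identifications from a shedding experiment
#'
#' The protein is split at every planted cleavage site into products; each
#' product is digested fully with each protease and peptides are retained
#' with probability `detection_prob`, mapped back to whole-protein
#' coordinates. Peptides abutting a planted site carry the non-canonical
#' terminus that the real experiment would reveal. Decoy peptides --
#' random substrings whose termini are non-canonical at non-planted
#' positions -- are added at `decoy_rate` times the number of true peptides.
#'
#' @param protein A `protein_record`.
#' @param planted_sites Residue indices of planted cleavage bonds.
#' @param proteases Named list of `protease_spec`s (default [default_proteases()]).
#' @param decoy_rate Decoys per true peptide (fraction, default 0).
#' @param detection_prob Retention probability per true peptide (default 1).
#' @param length_range Peptide length bounds used in the digests.
#' @param seed Integer seed.
#' @return List with `peptides` (table: `peptide`, `protein_id`, `protease`,
#'   `start`, `end`, `is_decoy`) and `truth` (`planted_sites`).
#' @export
simulate_shedding_identifications <- function(protein, planted_sites,
                                              proteases = default_proteases(),
                                              decoy_rate = 0,
                                              detection_prob = 1,
                                              length_range = c(5L, 30L),
                                              seed) {
  if (missing(seed)) stop("seed is required")
  n <- protein_length(protein)
  stopifnot(all(planted_sites >= 1L), all(planted_sites <= n - 1L),
            decoy_rate >= 0, decoy_rate <= 1,
            detection_prob >= 0, detection_prob <= 1)
  planted_sites <- sort(unique(as.integer(planted_sites)))
  bounds <- c(0L, planted_sites, n)

  tabs <- list()
  for (pr in proteases) {
    for (k in seq_len(length(bounds) - 1L)) {
      s0 <- bounds[k] + 1L; e0 <- bounds[k + 1L]
      frag <- protein_record(protein$id, substring(protein$sequence, s0, e0))
      d <- digest(frag, pr, "full", missed_cleavages = 0L,
                  length_range = c(1L, protein_length(frag)))
      if (nrow(d) == 0L) next
      d$start <- d$start + s0 - 1L
      d$end <- d$end + s0 - 1L
      # the length filter never removes a peptide abutting a planted bond:
      # those carry the cleavage evidence the experiment exists to detect
      len <- d$end - d$start + 1L
      boundary <- d$end %in% planted_sites | (d$start - 1L) %in% planted_sites
      d <- d[boundary | (len >= length_range[1] & len <= length_range[2]), ,
             drop = FALSE]
      tabs[[length(tabs) + 1L]] <- d
    }
  }
  peptides <- do.call(rbind, tabs)
  peptides$is_decoy <- FALSE

  local_seed(seed, {
    if (detection_prob < 1) {
      peptides <- peptides[stats::runif(nrow(peptides)) < detection_prob, ,
                           drop = FALSE]
    }
    n_decoy <- round(decoy_rate * nrow(peptides))
    if (n_decoy > 0L) {
      decoys <- list()
      guard <- 0L
      while (length(decoys) < n_decoy && guard < 100L * n_decoy) {
        guard <- guard + 1L
        len <- sample(seq(length_range[1], min(length_range[2], n - 2L)), 1L)
        s <- sample.int(n - len + 1L, 1L)
        e <- s + len - 1L
        # a decoy must not recreate evidence at a planted bond
        if ((e %in% planted_sites) || ((s - 1L) %in% planted_sites)) next
        pr_name <- sample(names(proteases), 1L)
        lab <- classify_termini(
          list(peptide = substring(protein$sequence, s, e), start = s, end = e),
          protein, proteases[[pr_name]])
        # decoys carry non-canonical termini at non-planted positions
        if (any(lab != "non_canonical")) next
        decoys[[length(decoys) + 1L]] <- data.frame(
          peptide = substring(protein$sequence, s, e),
          protein_id = protein$id, start = s, end = e,
          protease = pr_name, is_decoy = TRUE,
          stringsAsFactors = FALSE)
      }
      if (length(decoys)) {
        peptides <- rbind(peptides, do.call(rbind, decoys))
      }
    }
  })
  rownames(peptides) <- NULL
  list(peptides = peptides, truth = list(planted_sites = planted_sites))
}

# Non-physical positional intensity heuristic standing in for a learned
# fragment-intensity predictor: mid-sequence ions are strongest, y slightly
# stronger than b.
predict_intensities <- function(ions, peptide_len) {
  rel <- ions$index / peptide_len
  base <- exp(-((rel - 0.5)^2) / 0.08)
  base * ifelse(ions$series == "y", 1.3, 1.0) * 1000 / ions$charge
}

#' Simulate an acquired/predicted fragment-spectrum pair
#'
#' The predicted spectrum carries noiseless heuristic intensities at the
#' theoretical b/y m/z values. The acquired spectrum applies multiplicative
#' log-normal intensity noise (`noise_sd` on the log scale), Bernoulli peak
#' dropout, m/z jitter uniform within `jitter_frac` of the matching
#' tolerance, and uniform random background peaks.
#'
#' @param peptide Peptide sequence.
#' @param noise_sd Log-scale SD of the multiplicative intensity noise.
#' @param dropout Peak dropout probability; may also be a named vector
#'   `c(b = ..., y = ...)` for per-series dropout.
#' @param max_charge Fragment charges 1..max_charge.
#' @param tolerance_ppm Matching tolerance the jitter is scaled to.
#' @param jitter_frac Fraction of the tolerance used as jitter half-width.
#' @param n_background Number of uniform background peaks added.
#' @param seed Integer seed.
#' @return List with `acquired` and `predicted` `spectrum` objects.
#' @export
simulate_spectrum_pair <- function(peptide, noise_sd = 0.2, dropout = 0.1,
                                   max_charge = 2L, tolerance_ppm = 20,
                                   jitter_frac = 0.5, n_background = 5L,
                                   seed) {
  if (missing(seed)) stop("seed is required")
  ions <- theoretical_fragments(peptide, max_charge)
  pred_int <- predict_intensities(ions, nchar(peptide))
  predicted <- spectrum(ions$mz, pred_int, precursor_charge = max_charge,
                        peptide = peptide, label = "predicted")
  acq <- local_seed(seed, {
    drop_p <- if (length(dropout) == 1L) rep(dropout, nrow(ions))
              else unname(dropout[ions$series])
    keep <- stats::runif(nrow(ions)) >= drop_p
    mz <- ions$mz[keep]
    int <- pred_int[keep] * exp(stats::rnorm(sum(keep), 0, noise_sd))
    jit <- mz * tolerance_ppm * 1e-6 * jitter_frac
    mz <- mz + stats::runif(sum(keep), -jit, jit)
    if (n_background > 0L && length(ions$mz) > 0L) {
      bg_mz <- stats::runif(n_background, min(ions$mz), max(ions$mz) + 200)
      bg_int <- stats::runif(n_background, 0, stats::quantile(pred_int, 0.2))
      mz <- c(mz, bg_mz); int <- c(int, bg_int)
    }
    list(mz = mz, int = int)
  })
  if (length(acq$mz) == 0L) stop("all peaks dropped; lower the dropout rate")
  list(acquired = spectrum(acq$mz, acq$int, precursor_charge = max_charge,
                           peptide = peptide, label = "acquired"),
       predicted = predicted)
}

#' Simulate a label-free proteome intensity matrix
#'
#' Per-protein log2 intensities are normal around a protein-specific
#' baseline; a labelled subset of proteins is shifted between the two
#' groups by `effect_size` log2 units. Missingness is missing-not-at-random:
#' the probability a cell is missing is a decreasing logistic function of
#' its (pre-masking) intensity, mimicking low-abundance dropout.
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Samples per group (two groups).
#' @param effect_size Log2 shift applied to affected proteins (group A up).
#' @param frac_affected Fraction of proteins carrying the effect.
#' @param baseline_mean,baseline_sd Distribution of protein baselines (log2).
#' @param noise_sd Within-protein replicate SD (log2).
#' @param mnar_mid,mnar_scale Logistic missingness midpoint and scale on the
#'   log2-intensity axis; `mnar_max` caps the missingness probability.
#' @param seed Integer seed.
#' @return List with `matrix` (log2, `NA` = missing), `groups`,
#'   `affected` (logical truth per protein), `full_matrix` (pre-masking).
#' @export
simulate_proteome <- function(n_proteins = 1000L, n_per_group = 3L,
                              effect_size = 0, frac_affected = 0.1,
                              baseline_mean = 25, baseline_sd = 3,
                              noise_sd = 0.5,
                              mnar_mid = 21, mnar_scale = 1.5, mnar_max = 0.9,
                              seed) {
  if (missing(seed)) stop("seed is required")
  local_seed(seed, {
    groups <- rep(c("A", "B"), each = n_per_group)
    affected <- rep(FALSE, n_proteins)
    if (effect_size != 0 && frac_affected > 0) {
      affected[sample.int(n_proteins, round(frac_affected * n_proteins))] <- TRUE
    }
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    mu <- outer(base, rep(1, 2 * n_per_group))
    mu[affected, groups == "A"] <- mu[affected, groups == "A"] + effect_size
    full <- mu + matrix(stats::rnorm(n_proteins * 2 * n_per_group, 0, noise_sd),
                        n_proteins)
    p_miss <- mnar_max * stats::plogis(-(full - mnar_mid) / mnar_scale)
    obs <- full
    obs[matrix(stats::runif(length(full)), n_proteins) < p_miss] <- NA
    rownames(obs) <- rownames(full) <- paste0("protein_", seq_len(n_proteins))
    colnames(obs) <- colnames(full) <- paste0(groups, rep(seq_len(n_per_group), 2))
    list(matrix = obs, groups = groups, affected = affected, full_matrix = full)
  })
}

#' Simulate a shedding-assay fluorescence plate
#'
#' Each condition has a true shed fraction `f`: of a common total reporter
#' signal, `f` ends up in the supernatant and `1 - f` stays with the cells.
#' Well fluorescence is gain times the compartment signal plus additive
#' background plus normal noise, so the generator's ground truth
#' (`f / (1 - f)` relative to the control) is recoverable by
#' [shedding_ratio()].
#'
#' @param shed_fractions Named numeric vector: true shed fraction per
#'   condition (in `[0, 1)`); names are condition labels.
#' @param control_condition Which condition is the control.
#' @param n_wells Replicate wells per compartment.
#' @param total_signal Total reporter signal per condition (a.u.).
#' @param background Additive background fluorescence (a.u.).
#' @param gain Detector gain multiplying the signal.
#' @param noise_sd Additive well noise SD (a.u.).
#' @param seed Integer seed.
#' @return List with `plate` (data frame for [shedding_ratio()]),
#'   `background` (named vector) and `truth` (shed fractions and expected
#'   normalised ratios).
#' @export
simulate_plate <- function(shed_fractions, control_condition = names(shed_fractions)[1],
                           n_wells = 4L, total_signal = 1000, background = 100,
                           gain = 1, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(!is.null(names(shed_fractions)),
            all(shed_fractions >= 0), all(shed_fractions < 1),
            control_condition %in% names(shed_fractions))
  plate <- local_seed(seed, {
    rows <- list()
    for (cc in names(shed_fractions)) {
      f <- shed_fractions[[cc]]
      for (comp in c("supernatant", "cell")) {
        signal <- if (comp == "supernatant") f * total_signal else (1 - f) * total_signal
        fl <- gain * (signal + background) + stats::rnorm(n_wells, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cc, compartment = comp, fluorescence = pmax(0, fl),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  f0 <- shed_fractions[[control_condition]]
  odds <- shed_fractions / (1 - shed_fractions)
  list(plate = plate,
       background = c(supernatant = gain * background, cell = gain * background),
       truth = list(shed_fractions = shed_fractions,
                    control = control_condition,
                    expected_normalized = odds / (f0 / (1 - f0))))
}

#' Simulate a FRET cAMP trace with known anchors
#'
#' Builds a donor/acceptor pair whose corrected ratio follows a prescribed
#' response curve: baseline before ligand addition, a rise after it, and a
#' saturating plateau after the maximal stimulus. Bleed-through and additive
#' channel background are embedded so [fret_normalize()] can be validated by
#' round trip against the generator's ground-truth percent response.
#'
#' @param n_points Trace length.
#' @param ligand_index,stimulus_index Event positions.
#' @param baseline_ratio,plateau_ratio Corrected-ratio anchors (0% and 100%).
#' @param bleed_through Donor bleed-through fraction embedded in the
#'   acceptor channel.
#' @param background Named `c(donor = ..., acceptor = ...)` added to the
#'   channels.
#' @param donor_level Corrected donor channel level (a.u.).
#' @param noise_sd Additive channel noise SD (a.u.).
#' @param seed Integer seed.
#' @return List with `trace` (data frame `time`, `donor`, `acceptor`),
#'   event indices, `bleed_through`, `background`, and `truth`
#'   (`response_percent` per point).
#' @export
simulate_fret_trace <- function(n_points = 120L, ligand_index = 31L,
                                stimulus_index = 91L,
                                baseline_ratio = 1.0, plateau_ratio = 2.0,
                                bleed_through = 0.3,
                                background = c(donor = 50, acceptor = 80),
                                donor_level = 500, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(plateau_ratio > baseline_ratio, ligand_index > 10L,
            stimulus_index > ligand_index, stimulus_index < n_points)
  t_ <- seq_len(n_points)
  # ground-truth percent response: 0 before ligand, partial rise, then 100
  resp <- numeric(n_points)
  rise <- t_ >= ligand_index & t_ < stimulus_index
  resp[rise] <- 60 * (1 - exp(-(t_[rise] - ligand_index + 1) / 10))
  sat <- t_ >= stimulus_index
  resp[sat] <- 100 - (100 - resp[max(which(rise))]) * exp(-(t_[sat] - stimulus_index + 1) / 3)
  resp[(n_points - 9L):n_points] <- 100      # exact plateau anchor window
  ratio <- baseline_ratio + resp / 100 * (plateau_ratio - baseline_ratio)
  trace <- local_seed(seed, {
    donor <- rep(donor_level, n_points) + stats::rnorm(n_points, 0, noise_sd)
    acceptor_corr <- donor / ratio
    acceptor <- acceptor_corr + bleed_through * donor + background[["acceptor"]] +
      stats::rnorm(n_points, 0, noise_sd)
    data.frame(time = t_, donor = donor + background[["donor"]],
               acceptor = acceptor)
  })
  list(trace = trace, ligand_index = ligand_index,
       stimulus_index = stimulus_index, bleed_through = bleed_through,
       background = background,
       truth = list(response_percent = resp, baseline_ratio = baseline_ratio,
                    plateau_ratio = plateau_ratio))
}
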