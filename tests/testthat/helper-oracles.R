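# Independent brute-force oracles, deliberately written against the rule
# definitions rather than the package's algorithms.

# Every position p in [1, n-1] where the specificity rule holds.
oracle_cut_points <- function(sequence, cut_residues, side, blocked_next = character()) {
  aa <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  for (p in seq_len(length(aa) - 1L)) {
    hit <- if (side == "after") {
      aa[p] %in% cut_residues && !(aa[p + 1] %in% blocked_next)
    } else {
      aa[p + 1] %in% cut_residues
    }
    if (hit) out <- c(out, p)
  }
  out
}

# Exhaustive substring enumeration filtered by the terminus rule and the
# internal missed-cleavage count.
oracle_semi_digest <- function(sequence, cuts, missed, len_range) {
  n <- nchar(sequence)
  anchors <- c(0L, cuts, n)
  res <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1L
    if (len < len_range[1] || len > len_range[2]) next
    if (!((s - 1L) %in% anchors) && !(e %in% anchors)) next
    if (sum(cuts > s - 1L & cuts < e) > missed) next
    res[[length(res) + 1L]] <- c(s, e)
  }
  if (!length(res)) return(matrix(integer(0), ncol = 2))
  m <- unique(do.call(rbind, res))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Repeated-scan nearest-neighbour assignment: at each step pick the globally
# smallest |delta| among unassigned (ion, peak) pairs within tolerance,
# breaking ties towards the lower peak m/z.
oracle_match <- function(ion_mz, peak_mz, peak_int, tol_da) {
  assigned <- rep(0, length(ion_mz))
  free_ion <- rep(TRUE, length(ion_mz))
  free_peak <- rep(TRUE, length(peak_mz))
  repeat {
    best <- NULL
    for (i in which(free_ion)) for (p in which(free_peak)) {
      d <- abs(ion_mz[i] - peak_mz[p])
      if (d > tol_da) next
      if (is.null(best) || d < best$d ||
          (d == best$d && peak_mz[p] < peak_mz[best$p])) {
        best <- list(i = i, p = p, d = d)
      }
    }
    if (is.null(best)) break
    assigned[best$i] <- peak_int[best$p]
    free_ion[best$i] <- FALSE
    free_peak[best$p] <- FALSE
  }
  assigned
}

# Closed-form Benjamini-Hochberg step-up: adj_i = min_{j >= i} (p_(j) * m / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

synthetic_pthr1 <- function() {
  read_fasta(system.file("extdata", "pthr1_nterm_synthetic.fasta",
                         package = "shedmap"))[[1]]
}

# A fully concordant matched-fragment set with identical intensities.
identical_matched_set <- function(n = 10) {
  labels <- paste0("y", seq_len(n))
  out <- data.frame(label = labels, series = "y", index = seq_len(n),
                    mz1 = 100 + 10 * seq_len(n),
                    acquired = seq_len(n) * 10, predicted = seq_len(n) * 10,
                    stringsAsFactors = FALSE)
  class(out) <- c("matched_fragments", "data.frame")
  out
}

# Temp paths cleaned up when the calling test finishes.
withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}
withr_local_dir <- withr_local_file
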