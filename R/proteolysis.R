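AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein record
#'
#' A protein record holds an identifier and a sequence over the 20 standard
#' amino-acid letters. Coordinates throughout the package are 1-based and
#' inclusive. Nonstandard letters (B, J, O, U, X, Z) are rejected rather than
#' skipped: downstream mass computation would be undefined for them.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (single string, standard letters only).
#' @param description Optional FASTA description line (without the id).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("protein sequence must have length >= 1")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% AA_LETTERS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in protein '%s'",
                 letters[bad[1]], bad[1], id))
  }
  structure(list(id = id, sequence = sequence, description = description),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Protein length
#' @param protein A `protein_record`.
#' @return Integer number of residues.
#' @export
protein_length <- function(protein) nchar(protein$sequence)

#' Define a protease cleavage specificity
#'
#' A specificity rule names the residues at which the protease cuts and on
#' which side of them the scissile bond lies. `blocked_next` lists residues
#' that veto a cut when they immediately follow the cut residue (the classic
#' "not before proline" rule); an empty set means no veto, i.e. "/P"
#' behaviour in search-engine nomenclature.
#'
#' @param name Protease identifier, unique within a registry.
#' @param cut_residues Character vector of residue letters at which cuts occur.
#' @param side `"after"` (C-terminal to the cut residue) or `"before"`.
#' @param blocked_next Character vector of vetoing following residues.
#' @return An object of class `protease_spec`.
#' @export
protease_spec <- function(name, cut_residues, side = c("after", "before"),
                          blocked_next = character()) {
  side <- match.arg(side)
  cut_residues <- unique(toupper(cut_residues))
  blocked_next <- unique(toupper(blocked_next))
  if (length(cut_residues) == 0L) stop("cut_residues must be non-empty")
  stopifnot(all(cut_residues %in% AA_LETTERS), all(blocked_next %in% AA_LETTERS))
  structure(list(name = name, cut_residues = cut_residues, side = side,
                 blocked_next = blocked_next),
            class = "protease_spec")
}

#' Default protease registry
#'
#' The four enzymes used for the multi-protease semi-specific searches, with
#' the usual search-engine definitions: Trypsin/P cuts after K/R with no
#' proline veto, LysC after K, chymotrypsin after F/W/Y/L, AspN before D.
#' All rules are data: pass a modified list to any function that takes a
#' registry to change them per run.
#'
#' @return Named list of `protease_spec` objects.
#' @export
default_proteases <- function() {
  specs <- list(
    protease_spec("trypsinP",     c("K", "R"), "after"),
    protease_spec("lysC",         "K",         "after"),
    protease_spec("chymotrypsin", c("F", "W", "Y", "L"), "after"),
    protease_spec("aspN",         "D",         "before")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Enumerate cleavage points of a protease on a protein
#'
#' A cleavage point `p` denotes the bond between residues `p` and `p + 1`.
#' For a `side = "after"` enzyme, `p` is a cut iff residue `p` is a cut
#' residue and residue `p + 1` is not vetoed; for `side = "before"`, iff
#' residue `p + 1` is a cut residue.
#'
#' @param protein A `protein_record`.
#' @param protease A `protease_spec`.
#' @return Strictly increasing integer vector of cut positions in
#'   `[1, length - 1]` (possibly empty).
#' @export
enumerate_cleavage_points <- function(protein, protease) {
  stopifnot(inherits(protein, "protein_record"), inherits(protease, "protease_spec"))
  aa <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 2L) return(integer(0))
  p <- seq_len(n - 1L)
  if (protease$side == "after") {
    ok <- aa[p] %in% protease$cut_residues & !(aa[p + 1L] %in% protease$blocked_next)
  } else {
    ok <- aa[p + 1L] %in% protease$cut_residues
  }
  p[ok]
}

new_peptide_match <- function(peptide, protein_id, start, end, protease) {
  data.frame(peptide = peptide, protein_id = protein_id,
             start = as.integer(start), end = as.integer(end),
             protease = protease, stringsAsFactors = FALSE)
}

#' In-silico digestion of a protein
#'
#' Full specificity returns the maximal runs between consecutive cut points
#' (protein termini count as boundaries), merged across up to
#' `missed_cleavages` internal cuts. Semi specificity returns every substring
#' for which at least one terminus lies at a cut point or protein terminus
#' while the other may lie anywhere; the semi set is always a superset of the
#' full set at equal parameters.
#'
#' @param protein A `protein_record`.
#' @param protease A `protease_spec`.
#' @param specificity `"full"` or `"semi"`.
#' @param missed_cleavages Maximum internal (missed) cut points per peptide.
#' @param length_range Length 2 integer vector `c(min, max)`, `min >= 1`.
#' @return A data frame of peptide matches with columns `peptide`,
#'   `protein_id`, `start`, `end`, `protease`, sorted by `(start, end)`.
#' @export
digest <- function(protein, protease, specificity = c("full", "semi"),
                   missed_cleavages = 2L, length_range = c(6L, 40L)) {
  specificity <- match.arg(specificity)
  stopifnot(missed_cleavages >= 0L)
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[2] < length_range[1]) {
    stop("length_range must be c(min, max) with 1 <= min <= max")
  }
  n <- protein_length(protein)
  cuts <- enumerate_cleavage_points(protein, protease)
  bounds <- c(0L, cuts, n)            # peptide i spans (bounds[i]+1)..bounds[j]
  out <- list()
  k <- length(bounds)
  for (i in seq_len(k - 1L)) {
    jmax <- min(i + 1L + missed_cleavages, k)
    for (j in (i + 1L):jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j]
      len <- e - s + 1L
      if (len >= length_range[1] && len <= length_range[2]) {
        out[[length(out) + 1L]] <- c(s, e)
      }
    }
  }
  full <- if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)

  if (specificity == "semi") {
    cutset <- c(0L, cuts, n)          # terminus anchors (0 = protein N-term)
    semi <- list()
    for (s in seq_len(n)) {
      n_anchored <- (s - 1L) %in% cutset
      emin <- s + length_range[1] - 1L
      emax <- min(n, s + length_range[2] - 1L)
      if (emin > emax) next
      for (e in emin:emax) {
        c_anchored <- e %in% cutset
        if (!n_anchored && !c_anchored) next
        # internal missed cleavages: cut points strictly inside (s-1, e)
        internal <- sum(cuts > s - 1L & cuts < e)
        # an unanchored terminus sitting just past a cut does not consume it
        if (internal > missed_cleavages) next
        semi[[length(semi) + 1L]] <- c(s, e)
      }
    }
    full <- if (length(semi)) do.call(rbind, semi) else matrix(integer(0), ncol = 2)
  }

  if (nrow(full) == 0L) {
    return(new_peptide_match(character(0), character(0), integer(0),
                             integer(0), character(0)))
  }
  full <- unique(full)
  ord <- order(full[, 1], full[, 2])
  full <- full[ord, , drop = FALSE]
  new_peptide_match(substring(protein$sequence, full[, 1], full[, 2]),
                    protein$id, full[, 1], full[, 2], protease$name)
}

#' Classify the two termini of a peptide match
#'
#' Each terminus is labelled `protein_terminus` if it coincides with the
#' protein's own terminus, `protease_consistent` if it sits at a cleavage
#' point of the digestion protease, and `non_canonical` otherwise. A
#' non-canonical terminus is the footprint of a cleavage event not explained
#' by the digestion enzyme -- the signal this package exists to collect.
#'
#' @param match One-row data frame (or list) with `peptide`, `start`, `end`.
#' @param protein The `protein_record` the match refers to.
#' @param protease The `protease_spec` used for the digest.
#' @return Named character vector `c(n_term = ..., c_term = ...)`.
#' @export
classify_termini <- function(match, protein, protease) {
  start <- as.integer(match$start); end <- as.integer(match$end)
  n <- protein_length(protein)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop("peptide match inconsistent with protein coordinates")
  }
  if (substring(protein$sequence, start, end) != match$peptide) {
    stop(sprintf("peptide '%s' does not equal protein[%d..%d]",
                 match$peptide, start, end))
  }
  cuts <- enumerate_cleavage_points(protein, protease)
  n_lab <- if (start == 1L) "protein_terminus"
           else if ((start - 1L) %in% cuts) "protease_consistent"
           else "non_canonical"
  c_lab <- if (end == n) "protein_terminus"
           else if (end %in% cuts) "protease_consistent"
           else "non_canonical"
  c(n_term = n_lab, c_term = c_lab)
}
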