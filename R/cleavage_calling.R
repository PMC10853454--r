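#' Map a peptide onto a protein sequence
#'
#' Exact substring search; all occurrences are returned in ascending start
#' order so that multi-locus peptides can be flagged ambiguous downstream.
#'
#' @param protein A `protein_record`.
#' @param peptide Non-empty peptide string.
#' @return Data frame with columns `start`, `end` (1-based inclusive); zero
#'   rows when the peptide does not occur.
#' @export
map_peptide <- function(protein, peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  hits <- gregexpr(peptide, protein$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(hits),
             end = as.integer(hits) + nchar(peptide) - 1L)
}

#' Collect non-canonical terminus evidence from a peptide table
#'
#' Each peptide is evaluated against the protease it was digested with (each
#' digest is searched separately, so a terminus that would be canonical for a
#' *different* protease in the experiment still counts as evidence). A
#' peptide contributes one evidence record per non-canonical terminus: a
#' non-canonical C-terminus ending at residue `p` supports a cleavage at bond
#' `p | p+1` via the N-terminal product (`n_product_c_terminus`); a
#' non-canonical N-terminus starting at `p + 1` supports the same bond via
#' the C-terminal product (`c_product_n_terminus`). Peptides mapping to
#' multiple loci contribute one record per locus, flagged `ambiguous`.
#'
#' @param peptide_table Data frame with columns `peptide`, `protein_id`,
#'   `protease` and optional `start`/`end` (when absent or `NA`, the peptide
#'   is located by [map_peptide()]).
#' @param proteins Named list of `protein_record`s keyed by id.
#' @param proteases Named list of `protease_spec`s keyed by name.
#' @return Data frame of terminus evidence: `protein_id`, `site`,
#'   `product_side`, `peptide`, `protease`, `ambiguous`.
#' @export
collect_terminus_evidence <- function(peptide_table, proteins,
                                      proteases = default_proteases()) {
  required <- c("peptide", "protein_id", "protease")
  missing <- setdiff(required, names(peptide_table))
  if (length(missing)) {
    stop("peptide table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  unknown <- setdiff(unique(peptide_table$protease), names(proteases))
  if (length(unknown)) {
    stop("unknown protease(s): ", paste(unknown, collapse = ", "))
  }
  has_coords <- all(c("start", "end") %in% names(peptide_table))

  rows <- vector("list", nrow(peptide_table))
  for (i in seq_len(nrow(peptide_table))) {
    rec <- peptide_table[i, ]
    prot <- proteins[[rec$protein_id]]
    if (is.null(prot)) next
    if (has_coords && !is.na(rec$start) && !is.na(rec$end)) {
      loci <- data.frame(start = as.integer(rec$start), end = as.integer(rec$end))
    } else {
      loci <- map_peptide(prot, rec$peptide)
    }
    if (nrow(loci) == 0L) next
    ambiguous <- nrow(loci) > 1L
    spec <- proteases[[rec$protease]]
    for (j in seq_len(nrow(loci))) {
      m <- list(peptide = rec$peptide, start = loci$start[j], end = loci$end[j])
      lab <- classify_termini(m, prot, spec)
      ev <- list()
      if (lab[["c_term"]] == "non_canonical") {
        ev[[length(ev) + 1L]] <- data.frame(
          protein_id = prot$id, site = loci$end[j],
          product_side = "n_product_c_terminus",
          peptide = rec$peptide, protease = rec$protease,
          ambiguous = ambiguous, stringsAsFactors = FALSE)
      }
      if (lab[["n_term"]] == "non_canonical") {
        ev[[length(ev) + 1L]] <- data.frame(
          protein_id = prot$id, site = loci$start[j] - 1L,
          product_side = "c_product_n_terminus",
          peptide = rec$peptide, protease = rec$protease,
          ambiguous = ambiguous, stringsAsFactors = FALSE)
      }
      if (length(ev)) rows[[i]] <- rbind(rows[[i]], do.call(rbind, ev))
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), site = integer(0),
                      product_side = character(0), peptide = character(0),
                      protease = character(0), ambiguous = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protein_id, out$site, out$product_side, out$peptide,
            out$protease), , drop = FALSE]
}

#' Call cleavage sites from terminus evidence
#'
#' Evidence is aggregated per (protein, site). A call is *concordant* when
#' both cleavage products are seen: at least one peptide ending at the site
#' (N-terminal product) and at least one starting just after it (C-terminal
#' product). With `min_products = 2` only concordant calls are returned --
#' the rule that pinpoints a genuine shedding site among one-sided noise.
#'
#' @param evidence Data frame as returned by [collect_terminus_evidence()].
#' @param min_products 1 (any evidence) or 2 (concordant only).
#' @param min_proteases Minimum number of distinct proteases supporting the
#'   site (default 1).
#' @param include_ambiguous Count multi-locus peptides? Default `FALSE`.
#' @return Data frame sorted by `(protein_id, site)` with columns
#'   `protein_id`, `site`, `n_side_peptides`, `c_side_peptides` (each a
#'   `;`-joined deduplicated list), `n_n_side`, `n_c_side`, `proteases`,
#'   `concordant`.
#' @export
call_cleavage_sites <- function(evidence, min_products = 2L,
                                min_proteases = 1L,
                                include_ambiguous = FALSE) {
  stopifnot(min_products %in% c(1L, 2L))
  if (nrow(evidence) == 0L) {
    return(data.frame(protein_id = character(0), site = integer(0),
                      n_side_peptides = character(0),
                      c_side_peptides = character(0),
                      n_n_side = integer(0), n_c_side = integer(0),
                      proteases = character(0), concordant = logical(0)))
  }
  if (!include_ambiguous) evidence <- evidence[!evidence$ambiguous, , drop = FALSE]
  if (nrow(evidence) == 0L) return(call_cleavage_sites(evidence[0, ], min_products))

  key <- paste(evidence$protein_id, evidence$site, sep = "\r")
  calls <- lapply(split(evidence, key), function(ev) {
    n_pep <- sort(unique(ev$peptide[ev$product_side == "n_product_c_terminus"]))
    c_pep <- sort(unique(ev$peptide[ev$product_side == "c_product_n_terminus"]))
    data.frame(protein_id = ev$protein_id[1], site = ev$site[1],
               n_side_peptides = paste(n_pep, collapse = ";"),
               c_side_peptides = paste(c_pep, collapse = ";"),
               n_n_side = length(n_pep), n_c_side = length(c_pep),
               proteases = paste(sort(unique(ev$protease)), collapse = ";"),
               n_proteases = length(unique(ev$protease)),
               concordant = length(n_pep) > 0L && length(c_pep) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out <- out[out$n_proteases >= min_proteases, , drop = FALSE]
  if (min_products == 2L) out <- out[out$concordant, , drop = FALSE]
  out[order(out$protein_id, out$site), , drop = FALSE]
}
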