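#' Read protein records from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named list of `protein_record`s (keyed by id, the first
#'   whitespace-delimited token of the header; the remainder is kept as the
#'   description).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), desc[i])
  })
  stats::setNames(recs, ids)
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns; descriptions are appended to the
#' header after the id.
#'
#' @param proteins A `protein_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  set <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(set) <- vapply(proteins, function(p) {
    if (nzchar(p$description)) paste(p$id, p$description) else p$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read spectra from an MGF peak-list file
#'
#' Supports the BEGIN IONS / END IONS block structure with TITLE, PEPMASS,
#' CHARGE and SEQ keys followed by `m/z intensity` peak lines.
#'
#' @param path MGF file path.
#' @return List of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- NA_integer_
  title <- NA_character_; charge <- 1L; pep <- NA_character_
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i)
      in_block <- TRUE; block_start <- i
      title <- sprintf("spectrum_%d", length(spectra) + 1L)
      charge <- 1L; pep <- NA_character_
      mz <- numeric(0); int <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i)
      spectra[[length(spectra) + 1L]] <-
        spectrum(mz, int, precursor_charge = charge, peptide = pep, label = title)
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") title <- val
      else if (key == "CHARGE") charge <- as.integer(gsub("[^0-9]", "", val))
      else if (key == "SEQ") pep <- val
      # PEPMASS and other keys are accepted and ignored
    } else if (in_block) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) < 2L || anyNA(v[1:2])) {
        stop("malformed peak line ", i, " in block starting at line ", block_start)
      }
      mz <- c(mz, v[1]); int <- c(int, v[2])
    } else {
      stop("content outside BEGIN IONS/END IONS block at line ", i)
    }
  }
  if (in_block) {
    stop("missing END IONS for block starting at line ", block_start)
  }
  spectra
}

#' Write spectra to an MGF peak-list file
#'
#' @param spectra A `spectrum` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$label), con)
    writeLines(paste0("CHARGE=", sp$precursor_charge, "+"), con)
    if (!is.na(sp$peptide)) writeLines(paste0("SEQ=", sp$peptide), con)
    writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a tab-separated table with required columns
#'
#' @param path TSV path (UTF-8, header row).
#' @param required Character vector of columns that must be present.
#' @return Data frame.
#' @export
read_table_tsv <- function(path, required = character()) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' Write a data frame as a tab-separated table
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an intensity matrix from TSV
#'
#' First column holds protein ids; remaining columns are samples. Empty
#' cells and `NA` are treated as missing.
#'
#' @param path TSV path.
#' @return Numeric matrix with protein rownames.
#' @export
read_intensity_matrix <- function(path) {
  tab <- read_table_tsv(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}
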