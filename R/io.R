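# File formats: proteome FASTA, quantification report TSV, design TSV,
# gene-set lists, abundance-matrix TSV. All tabular formats are
# tab-separated, UTF-8, '.' decimal.

REPORT_COLUMNS <- c("sample_id", "species", "sequence", "modifications",
                    "charge", "genes", "intensity", "q_value")

#' Read a proteome FASTA
#'
#' Accepts UniProt-style headers (`sp|ACC|NAME ... GN=GENE`) and a simple
#' `>ACC GN=GENE` dialect. The gene symbol is taken from the `GN=` field; if
#' absent, the accession is used and a warning is issued.
#'
#' @param path FASTA file.
#' @param species species identifier to attach.
#' @return object of class `proteome`: list with `species` and `entries`
#'   (data.frame: accession, gene, sequence).
#' @export
read_proteome_fasta <- function(path, species) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  acc <- vapply(strsplit(headers, " ", fixed = TRUE), `[[`, "", 1L)
  uniprot <- grepl("^(sp|tr)\\|", acc)
  acc[uniprot] <- vapply(strsplit(acc[uniprot], "|", fixed = TRUE), `[[`, "", 2L)
  gene <- rep(NA_character_, length(headers))
  has_gn <- grepl("GN=", headers, fixed = TRUE)
  gene[has_gn] <- sub("^.*GN=([^ ]+).*$", "\\1", headers[has_gn])
  if (any(!has_gn)) {
    warning(sprintf("%d FASTA entries lack a GN= gene symbol; using accession",
                    sum(!has_gn)), call. = FALSE)
    gene[!has_gn] <- acc[!has_gn]
  }
  entries <- data.frame(accession = acc, gene = gene,
                        sequence = toupper(as.character(seqs)),
                        stringsAsFactors = FALSE)
  stop_if_not(all(nzchar(entries$sequence)), "empty sequence in %s", path)
  structure(list(species = species, entries = entries), class = "proteome")
}

#' Write a proteome FASTA
#'
#' Emits the simple `>ACC GN=GENE` header dialect understood by
#' [read_proteome_fasta()].
#'
#' @param proteome a `proteome` object.
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  e <- proteome$entries
  lines <- character(2L * nrow(e))
  lines[c(TRUE, FALSE)] <- sprintf(">%s GN=%s", e$accession, e$gene)
  lines[c(FALSE, TRUE)] <- e$sequence
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d entries, %d genes\n", x$species,
              nrow(x$entries), length(unique(x$entries$gene))))
  invisible(x)
}

#' Read a peptide-level quantification report
#'
#' Long-format TSV with one row per (sample, precursor) observation. A
#' precursor is identified by (sequence, modifications, charge); `genes` is a
#' semicolon-separated list of gene symbols the precursor maps to in the
#' spectral library.
#'
#' @param path TSV file with header columns `sample_id`, `species`,
#'   `sequence`, `modifications`, `charge`, `genes`, `intensity`, `q_value`.
#' @return data.frame of typed rows (a QuantReport).
#' @export
read_quant_report <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(REPORT_COLUMNS, names(df))
  stop_if_not(length(missing_cols) == 0, "report is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  stop_if_not(nrow(df) > 0, "no observations in report %s", path)
  df <- df[REPORT_COLUMNS]
  df$charge <- as.integer(df$charge)
  df$intensity <- as.numeric(df$intensity)
  df$q_value <- as.numeric(df$q_value)
  if (anyNA(df$intensity)) {
    stop(sprintf("non-numeric intensity at data line %d",
                 which(is.na(df$intensity))[1L]), call. = FALSE)
  }
  if (anyNA(df$q_value) || any(df$q_value < 0 | df$q_value > 1)) {
    bad <- which(is.na(df$q_value) | df$q_value < 0 | df$q_value > 1)[1L]
    stop(sprintf("invalid q_value at data line %d", bad), call. = FALSE)
  }
  key <- paste(df$sample_id, report_precursor_keys(df), sep = "::")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (sample, precursor) at data line %d",
                 which(duplicated(key))[1L]), call. = FALSE)
  }
  df
}

#' @rdname read_quant_report
#' @param report a QuantReport data.frame.
#' @export
write_quant_report <- function(report, path) {
  utils::write.table(report[REPORT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample design table
#'
#' TSV with columns `sample_id`, `species`, `group` mapping each sample to a
#' species and each species to a comparison group (e.g. rodent/primate).
#'
#' @param path TSV file.
#' @return data.frame with one row per sample.
#' @export
read_design <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("sample_id", "species", "group"), names(df))
  stop_if_not(length(missing_cols) == 0, "design is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  stop_if_not(!anyDuplicated(df$sample_id), "duplicate sample_id in design")
  sp_group <- unique(df[c("species", "group")])
  stop_if_not(!anyDuplicated(sp_group$species),
              "a species is assigned to more than one group")
  df
}

#' @rdname read_design
#' @param design a design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[c("sample_id", "species", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set file
#'
#' One gene symbol per line (or a single-column TSV, with or without a
#' header line named `gene`). Symbols are upper-cased and de-duplicated.
#'
#' @param path text file.
#' @return character vector of unique, upper-cased symbols.
#' @export
read_gene_set <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(vapply(strsplit(lines, "\t", fixed = TRUE),
                         function(x) if (length(x)) x[1L] else "", ""))
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(lines[1L]) == "gene") lines <- lines[-1L]
  stop_if_not(length(lines) > 0, "gene-set file %s is empty", path)
  unique(toupper(lines))
}

#' Write / read an abundance matrix as TSV
#'
#' Features in rows, samples in columns; the first column (`feature`) holds
#' the row names.
#'
#' @param x abundance matrix.
#' @param path TSV file.
#' @param scale scale flag to attach on read.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, scale = "linear") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  abundance_matrix(m, scale)
}
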