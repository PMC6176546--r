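# In-silico tryptic digestion, cross-species conserved-peptide indexing and
# counting of theoretically observable peptides for iBAQ.

#' Digestion parameters
#'
#' Parameters of the in-silico tryptic digest used both for peptide
#' identification-style digestion (defaults: minimum length 6, at most two
#' missed cleavages) and for conservation testing. Trypsin cleaves C-terminal
#' of K or R; under the default `"trypsin_blocked_by_proline"` rule a K/R
#' followed by proline is not cleaved, while `"trypsin_p"` cleaves regardless.
#'
#' @param enzyme_rule cleavage rule.
#' @param max_missed_cleavages maximum internal uncleaved K/R sites per peptide.
#' @param min_length minimum peptide length (residues).
#' @param max_length maximum peptide length, `Inf` for unbounded.
#' @return object of class `digest_params`.
#' @export
digest_params <- function(enzyme_rule = c("trypsin_blocked_by_proline", "trypsin_p"),
                          max_missed_cleavages = 2L,
                          min_length = 6L,
                          max_length = Inf) {
  enzyme_rule <- match.arg(enzyme_rule)
  stop_if_not(max_missed_cleavages >= 0, "max_missed_cleavages must be >= 0")
  stop_if_not(min_length >= 1, "min_length must be >= 1")
  stop_if_not(max_length >= min_length, "max_length must be >= min_length")
  structure(list(
    enzyme_rule = enzyme_rule,
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_length = as.integer(min_length),
    max_length = max_length
  ), class = "digest_params")
}

#' iBAQ observability parameters
#'
#' Bounds on "theoretically observable" fully-tryptic peptides used as the
#' iBAQ denominator: peptides of 7--30 residues at 0 missed cleavages by
#' default.
#'
#' @param min_length,max_length peptide length bounds (residues).
#' @param missed_cleavages missed cleavages allowed for observable peptides.
#' @return object of class `ibaq_params`.
#' @export
ibaq_params <- function(min_length = 7L, max_length = 30L, missed_cleavages = 0L) {
  stop_if_not(min_length >= 1, "min_length must be >= 1")
  stop_if_not(min_length <= max_length, "min_length must be <= max_length")
  stop_if_not(missed_cleavages >= 0, "missed_cleavages must be >= 0")
  structure(list(
    min_length = as.integer(min_length),
    max_length = as.integer(max_length),
    missed_cleavages = as.integer(missed_cleavages)
  ), class = "ibaq_params")
}

# 1-based positions of residues after which trypsin cleaves.
cleavage_sites <- function(residues, enzyme_rule) {
  n <- length(residues)
  kr <- which(residues == "K" | residues == "R")
  kr <- kr[kr < n]  # the C-terminus is a boundary anyway, not a "site"
  if (enzyme_rule == "trypsin_blocked_by_proline" && length(kr)) {
    kr <- kr[residues[kr + 1L] != "P"]
  }
  kr
}

#' In-silico tryptic digestion of one sequence
#'
#' Cleaves after every K/R (subject to the enzyme rule), then joins up to
#' `max_missed_cleavages` consecutive fragments and applies the length
#' bounds.
#'
#' @param sequence uppercase amino-acid string.
#' @param params a [digest_params()] object.
#' @return data.frame with columns `peptide`, `missed` (internal missed
#'   cleavage count) and `start` (0-based position in the sequence), ordered
#'   by start position then peptide end.
#' @examples
#' digest_sequence("MAGKRTESTKLLP", digest_params())
#' @export
digest_sequence <- function(sequence, params = digest_params()) {
  stop_if_not(is.character(sequence) && length(sequence) == 1L && nzchar(sequence),
              "sequence must be a single non-empty string")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!residues %in% LETTERS)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d", residues[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  sites <- cleavage_sites(residues, params$enzyme_rule)
  # fragment boundaries: starts and ends (1-based, inclusive)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, length(residues))
  nfrag <- length(starts)
  out_pep <- character(0); out_mc <- integer(0); out_start <- integer(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + params$max_missed_cleavages)
    for (j in i:jmax) {
      len <- ends[j] - starts[i] + 1L
      if (len < params$min_length || len > params$max_length) next
      out_pep <- c(out_pep, substr(sequence, starts[i], ends[j]))
      out_mc <- c(out_mc, j - i)
      out_start <- c(out_start, starts[i] - 1L)
    }
  }
  out <- data.frame(peptide = out_pep, missed = out_mc, start = out_start,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$start + nchar(out$peptide)), , drop = FALSE]
}

# Digest all entries of a proteome; returns data.frame(peptide, gene).
digest_proteome <- function(proteome, params) {
  entries <- proteome$entries
  peps <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    d <- digest_sequence(entries$sequence[i], params)
    if (nrow(d)) peps[[i]] <- data.frame(peptide = d$peptide,
                                         gene = entries$gene[i],
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, peps)
  if (is.null(res)) res <- data.frame(peptide = character(0), gene = character(0))
  unique(res)
}

#' Build a cross-species conserved-peptide index
#'
#' Digests every proteome with the same parameters and records, per peptide
#' sequence, the set of species in whose digest it occurs and the genes it
#' maps to per species. A peptide is "conserved" across a species set when it
#' occurs in the digest of every species in that set.
#'
#' @param proteomes named list of proteome objects (see
#'   [read_proteome_fasta()]); names are the species identifiers.
#' @param params a [digest_params()] object.
#' @return object of class `conserved_index`.
#' @export
build_conserved_index <- function(proteomes, params = digest_params()) {
  stop_if_not(length(proteomes) >= 2, "need at least two proteomes")
  species <- names(proteomes) %||% vapply(proteomes, function(p) p$species, "")
  if (is.null(names(proteomes))) names(proteomes) <- species
  stop_if_not(!anyDuplicated(species), "duplicate species identifiers")
  digests <- lapply(proteomes, digest_proteome, params = params)
  structure(list(
    species = species,
    peptides = lapply(digests, function(d) unique(d$peptide)),
    genes = digests,
    params = params
  ), class = "conserved_index")
}

#' @export
print.conserved_index <- function(x, ...) {
  cat("Conserved-peptide index over", length(x$species), "species:",
      paste(x$species, collapse = ", "), "\n")
  for (s in x$species) cat(sprintf("  %-10s %d peptides\n", s, length(x$peptides[[s]])))
  all_cons <- is_conserved(x$peptides[[1L]], x, x$species)
  cat(sprintf("  conserved in all species: %d\n", sum(all_cons)))
  invisible(x)
}

#' Test peptides for conservation across a species subset
#'
#' @param peptides character vector of bare peptide sequences.
#' @param index a [build_conserved_index()] result.
#' @param species_subset species that must all contain each peptide.
#' @return logical vector, one element per peptide.
#' @export
is_conserved <- function(peptides, index, species_subset = index$species) {
  stop_if_not(length(species_subset) >= 1, "species_subset must be non-empty")
  unknown <- setdiff(species_subset, index$species)
  stop_if_not(length(unknown) == 0, "unknown species: %s",
              paste(unknown, collapse = ", "))
  out <- rep(TRUE, length(peptides))
  for (s in species_subset) {
    out <- out & (peptides %in% index$peptides[[s]])
  }
  out
}

#' Count theoretically observable tryptic peptides (iBAQ denominator)
#'
#' @param sequence uppercase amino-acid string.
#' @param ibaq an [ibaq_params()] object.
#' @param enzyme_rule cleavage rule, as in [digest_params()].
#' @return count of distinct tryptic peptides within the length bounds.
#' @export
count_observable_peptides <- function(sequence, ibaq = ibaq_params(),
                                      enzyme_rule = "trypsin_blocked_by_proline") {
  d <- digest_sequence(sequence, digest_params(
    enzyme_rule = enzyme_rule,
    max_missed_cleavages = ibaq$missed_cleavages,
    min_length = ibaq$min_length,
    max_length = ibaq$max_length
  ))
  length(unique(d$peptide))
}
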