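#' Satellite DNA family
#'
#' A satDNA family is its identifier plus the consensus monomer sequence
#' against which copies are annotated and divergence is measured.
#'
#' @param family_id Short label, e.g. \code{"TmSat01"}.
#' @param consensus DNA string over \{A,C,G,T,N\}; lowercase is uppercased.
#' @param coerce_n Mask non-ACGTN ambiguity codes to N instead of erroring.
#' @return A list of class \code{"sat_family"} with fields \code{family_id},
#'   \code{consensus}, \code{monomer_length}.
#' @examples
#' fam <- sat_family("TmSat01", paste(rep("ACGT", 8), collapse = ""))
#' fam$monomer_length
#' @export
sat_family <- function(family_id, consensus, coerce_n = FALSE) {
  stopifnot(is.character(family_id), length(family_id) == 1L, nzchar(family_id))
  consensus <- check_dna(consensus, paste0("consensus of ", family_id), coerce_n)
  if (nchar(consensus) == 0L) stop("empty consensus for ", family_id)
  structure(
    list(family_id = family_id,
         consensus = consensus,
         monomer_length = nchar(consensus)),
    class = "sat_family"
  )
}

#' @export
print.sat_family <- function(x, ...) {
  cat(sprintf("satDNA family %s: %d bp monomer\n", x$family_id, x$monomer_length))
  invisible(x)
}

#' Read a FASTA file of satDNA family consensus sequences
#'
#' Record identifiers become family ids (text up to the first whitespace).
#'
#' @param path FASTA file.
#' @param coerce_n Mask ambiguity codes to N.
#' @return Named list of \code{\link{sat_family}} objects.
#' @export
read_families <- function(path, coerce_n = FALSE) {
  seqs <- read_fasta(path)
  if (anyDuplicated(names(seqs))) stop("duplicate family ids in ", path)
  fams <- lapply(names(seqs), function(id) sat_family(id, seqs[[id]], coerce_n))
  setNames(fams, names(seqs))
}

#' Read a FASTA file
#'
#' @param path FASTA file; arbitrary line wrapping; lowercase normalised to
#'   uppercase. An empty file yields an empty collection with a warning.
#' @return Named character vector of uppercase sequences. Names are truncated
#'   at the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (", path, "): line 1 is not a '>' header")
  }
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or named list) of DNA strings.
#' @param path Output path.
#' @param width Line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- unlist(seqs)
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Quality strings are not used by the counting stage (mismatch-count
#' criterion only) and are dropped.
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write reads to a FASTQ file with uniform placeholder qualities
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  quals <- Biostrings::BStringSet(vapply(
    nchar(seqs), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}
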