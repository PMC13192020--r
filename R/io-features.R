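# Feature tables (monomer hits, arrays) are plain data.frames with columns
#   seq_id, start, end, strand, family_id, divergence
# Internal coordinates are 0-based half-open on the forward strand throughout
# the package; conversion to 1-based inclusive happens only in the GFF3 writer.

check_features <- function(feat) {
  need <- c("seq_id", "start", "end", "strand", "family_id", "divergence")
  miss <- setdiff(need, names(feat))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(feat$end <= feat$start)
  if (length(bad)) {
    stop("feature with end <= start: ",
         paste0(feat$seq_id[bad[1]], ":", feat$start[bad[1]], "-", feat$end[bad[1]],
                " (", feat$family_id[bad[1]], ")"))
  }
  if (!all(feat$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(feat)
}

#' Write features as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are emitted verbatim. The score column carries divergence scaled by 1000.
#'
#' @param feat Feature data.frame (see \code{\link{find_monomers}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(feat, path) {
  if (nrow(feat) == 0L) {
    writeLines("#seq_id\tstart\tend\tname\tscore\tstrand", path)
    return(invisible(path))
  }
  check_features(feat)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   feat$seq_id, feat$start, feat$end, feat$family_id,
                   as.integer(round(feat$divergence * 1000)), feat$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file back into a feature table
#'
#' Inverse of \code{\link{write_bed}} for the fields the pipeline uses.
#'
#' @param path BED6 file.
#' @return Feature data.frame with 0-based half-open coordinates.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), family_id = character(0),
                      divergence = numeric(0)))
  }
  f <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("seq_id", "start", "end", "name", "score", "strand"))
  data.frame(seq_id = f$seq_id, start = as.integer(f$start), end = as.integer(f$end),
             strand = f$strand, family_id = f$name,
             divergence = f$score / 1000, stringsAsFactors = FALSE)
}

#' Write features as GFF3
#'
#' GFF3 is 1-based inclusive: a feature at internal \[start, end) becomes
#' \code{start+1 .. end}. Divergence travels in the attributes column.
#'
#' @param feat Feature data.frame.
#' @param path Output path.
#' @param type GFF3 type column value.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(feat, path, type = "satellite_DNA") {
  header <- "##gff-version 3"
  if (nrow(feat) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  check_features(feat)
  lines <- sprintf("%s\tsatkit\t%s\t%d\t%d\t.\t%s\t.\tfamily=%s;divergence=%.4f",
                   feat$seq_id, type, feat$start + 1L, feat$end, feat$strand,
                   feat$family_id, feat$divergence)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a satkit GFF3 file back into a feature table
#'
#' @param path GFF3 file written by \code{\link{write_gff3}}.
#' @return Feature data.frame with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(read_bed(tempfile_empty_bed()))
  }
  f <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    sub(paste0(key, "="), "", m)
  }
  data.frame(seq_id = f$V1,
             start = as.integer(f$V4) - 1L,
             end = as.integer(f$V5),
             strand = f$V7,
             family_id = attr_field(f$V9, "family"),
             divergence = as.numeric(attr_field(f$V9, "divergence")),
             stringsAsFactors = FALSE)
}

tempfile_empty_bed <- function() {
  p <- tempfile(fileext = ".bed")
  writeLines("#empty", p)
  p
}
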