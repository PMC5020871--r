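# Shared readers/writers: FASTA (80-column wrap, upper case, key=value header
# annotations), AGP v2.0 and headered TSV. All round-trip lossless.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector (upper-cased); full headers (with any
#'   `key=value` annotations) are kept as names.
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write a FASTA file
#'
#' @param seqs named character vector; names become headers and may carry
#'   `key=value` annotations.
#' @param path file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  writeXStringSet(x, path, width = width)
  invisible(path)
}

# Parse "id key=value key=value" FASTA headers into a list.
parse_fasta_header <- function(header) {
  parts <- strsplit(header, "\\s+")[[1L]]
  ann <- list(id = parts[1L])
  for (p in parts[-1L]) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) ann[[kv[1L]]] <- kv[2L]
  }
  ann
}

#' Write a TSV file with a header row
#' @param df data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV file
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write pseudomolecules as AGP v2.0
#'
#' One object per pseudomolecule; component lines carry the piece id and
#' orientation, gap lines are `100 contig yes map` (open gaps are written as
#' 100-bp gaps with map evidence). Coordinates are 1-based inclusive.
#'
#' @param pseudos list of `pseudomolecule` objects
#'   (see [build_pseudomolecules()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(pseudos, path) {
  lines <- c("##agp-version\t2.0")
  for (ps in pseudos) {
    pos <- 0L
    part <- 0L
    for (comp in ps$components) {
      part <- part + 1L
      if (comp$type == "gap") {
        lines <- c(lines, paste(ps$chrom, pos + 1L, pos + comp$length, part,
                                "N", comp$length, "contig", "yes", "map",
                                sep = "\t"))
      } else {
        lines <- c(lines, paste(ps$chrom, pos + 1L, pos + comp$length, part,
                                "W", comp$id, 1L, comp$length,
                                comp$orientation, sep = "\t"))
      }
      pos <- pos + comp$length
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP v2.0 file
#' @param path file path.
#' @return data.frame of component and gap lines.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 9L)
  if (length(bad)) stop("malformed AGP line ", bad[1L], " in ", path)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "f6", "f7", "f8", "f9")
  for (col in c("object_beg", "object_end", "part_number")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}
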