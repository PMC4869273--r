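#' Read paired or single FASTQ into a read table
#'
#' Gzip-transparent.  The mate is parsed from a trailing `/1` or `/2` on the
#' read name; reads without the suffix are `"unpaired"`.  Base qualities are
#' not used by the pipeline and are discarded.
#'
#' @param path FASTQ path (optionally `.gz`).
#' @return data frame with columns `read_id`, `mate`, `sequence`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(ss))
  mate <- rep("unpaired", length(ids))
  m <- regmatches(ids, regexpr("/[12]$", ids))
  has <- grepl("/[12]$", ids)
  mate[has] <- sub("/", "", m)
  data.frame(read_id = sub("/[12]$", "", ids), mate = mate,
             sequence = unname(normalise_seq(as.character(ss))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table as FASTQ
#'
#' Constant base quality `I` is emitted (qualities are unused by the
#' pipeline but kept for format fidelity).
#'
#' @param reads data frame with `read_id`, `mate`, `sequence`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_reads(reads)
  suffix <- ifelse(reads$mate %in% c("1", "2"), paste0("/", reads$mate), "")
  lines <- as.vector(rbind(paste0("@", reads$read_id, suffix),
                           reads$sequence, "+",
                           strrep("I", nchar(reads$sequence))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Split a read table into mate-1 and mate-2 FASTQ files
#'
#' @param reads data frame with `read_id`, `mate`, `sequence`.
#' @param prefix output path prefix; files are `<prefix>_1.fastq[.gz]` and
#'   `<prefix>_2.fastq[.gz]`.
#' @param gzip compress output?
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  write_fastq(reads[reads$mate == "1", , drop = FALSE], p1)
  write_fastq(reads[reads$mate == "2", , drop = FALSE], p2)
  invisible(c(p1, p2))
}
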