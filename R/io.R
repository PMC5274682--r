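# FASTA / BED / GFF3 / TSV input and output.  Internal coordinates are
# 1-based inclusive; BED and bedGraph output is 0-based half-open.

#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' residues are uppercased and any symbol outside A/C/G/T/N (IUPAC
#' ambiguity codes, gaps, ...) is replaced by N with a message reporting
#' the count.
#'
#' @param path FASTA file (single or multi record).
#' @return named character vector of DNA strings, in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1)
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_sub <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_sub > 0)
    message(n_sub, " non-ACGTN symbols replaced by N")
  cleaned
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s))
      writeLines(substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1,
                                nchar(s))), con)
  }
  invisible(path)
}

#' Write detected regions to BED6 / GFF3 / TSV
#'
#' BED6 uses 0-based half-open coordinates, name `period=n` and the score
#' column rounded and capped at 1000; GFF3 carries period, mFmax, Z and
#' consensus as attributes; the TSV is the flat table of
#' `as.data.frame()` and round-trips through [read_regions_tsv()].
#'
#' @param regions a `periodic_regions` object or its data.frame.
#' @param prefix output path prefix; files `<prefix>.bed`,
#'   `<prefix>.gff3`, `<prefix>.tsv` are written.
#' @param formats subset of `c("bed", "gff3", "tsv")`.
#' @return (invisibly) the written paths.
#' @export
write_regions <- function(regions, prefix,
                          formats = c("bed", "gff3", "tsv")) {
  df <- if (is.data.frame(regions)) regions else as.data.frame(regions)
  written <- character(0)
  if ("bed" %in% formats) {
    p <- paste0(prefix, ".bed")
    lines <- if (nrow(df)) sprintf("%s\t%d\t%d\tperiod=%d\t%d\t+",
                                   df$seq_id, df$start - 1L, df$end,
                                   df$period,
                                   pmin(1000L, as.integer(round(df$mF_max))))
             else character(0)
    writeLines(lines, p)
    written <- c(written, p)
  }
  if ("gff3" %in% formats) {
    p <- paste0(prefix, ".gff3")
    header <- "##gff-version 3"
    lines <- if (nrow(df)) sprintf(
      "%s\tperiscan\ttandem_repeat\t%d\t%d\t%.3f\t+\t.\tperiod=%d;mFmax=%.3f;Z=%.3f;consensus=%s",
      df$seq_id, df$start, df$end, df$mF_max, df$period, df$mF_max,
      df$triplet_Z, df$consensus) else character(0)
    writeLines(c(header, lines), p)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    p <- paste0(prefix, ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read a region TSV written by [write_regions()]
#' @param path TSV path.
#' @return data.frame with the region table.
#' @export
read_regions_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a BED file as a region data.frame
#'
#' Converts 0-based half-open BED intervals to the package's 1-based
#' inclusive convention.  Only the first three (plus optional name)
#' columns are used.
#'
#' @param path BED file.
#' @return data.frame with `seq_id`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- data.frame(seq_id = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  out
}
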