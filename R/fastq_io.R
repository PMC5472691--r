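# Minimal lossless FASTQ I/O (Phred+33, gzip by extension) with
# record-naming errors, plus TSV helpers shared by the pipeline.

#' Read a FASTQ file
#'
#' @param path file path; `.gz` handled transparently.
#' @return data.frame `id`, `seq`, `qual` (empty for an empty file).
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    .hb_stop("malformed FASTQ (", path, "): ", length(lines),
             " lines, not a multiple of 4")
  }
  i <- seq(1, length(lines), by = 4)
  if (!all(startsWith(lines[i], "@")) || !all(startsWith(lines[i + 2], "+"))) {
    bad <- i[!startsWith(lines[i], "@")][1]
    if (is.na(bad)) bad <- (i + 2)[!startsWith(lines[i + 2], "+")][1]
    .hb_stop("malformed FASTQ (", path, ") near line ", bad)
  }
  id <- sub("^@", "", lines[i])
  seq <- lines[i + 1]
  qual <- lines[i + 3]
  mism <- nchar(seq) != nchar(qual)
  if (any(mism)) {
    w <- which(mism)[1]
    .hb_stop("record '", id[w], "' (", path, ", line ", i[w],
             "): sequence and quality lengths differ")
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data.frame `id`, `seq`, `qual`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @export
write_fastq <- function(records, path) {
  mism <- nchar(records$seq) != nchar(records$qual)
  if (any(mism)) {
    .hb_stop("record '", records$id[which(mism)[1]],
             "': sequence and quality lengths differ")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n",
                    records$qual), con)
  invisible(path)
}

# uniform TSV writer (tab-separated, header, '.' decimal)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
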