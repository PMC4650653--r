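#' Read a FASTA file into a named list of chromosome sequences
#'
#' Sequences are uppercase-normalized and validated against the {A,C,G,T,N}
#' alphabet. Duplicate headers and illegal characters raise format errors
#' naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence; names are the
#'   first whitespace-delimited token of each header. Attribute
#'   \code{total_length} holds the summed length.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty FASTA file: %s", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stopf("malformed FASTA %s: line 1 does not start with '>'", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    line <- which(hdr)[which(duplicated(ids))[1L]]
    stopf("malformed FASTA %s: duplicate header '%s' at line %d", path, dup, line)
  }
  grp <- cumsum(hdr)
  body <- !hdr
  seqs <- vapply(split(lines[body], grp[body]), paste, character(1), collapse = "")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("malformed FASTA %s: illegal character in record '%s' (near line %d)",
          path, ids[i], which(hdr)[i])
  }
  out <- setNames(as.character(seqs), ids)
  if (any(nchar(out) == 0L)) {
    stopf("malformed FASTA %s: zero-length record '%s'", path, ids[nchar(out) == 0L][1L])
  }
  attr(out, "total_length") <- sum(nchar(out))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param line_width Characters per sequence line.
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    n <- nchar(s)
    starts <- seq(1L, n, by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (4-line records, no wrapping).
#' @return data.frame with columns read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stopf("malformed FASTQ %s: line count not divisible by 4", path)
  idx <- seq(1L, length(lines), by = 4L)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  data.frame(read_id = ids, seq = toupper(lines[idx + 1L]), qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with read_id, seq and optionally qual columns.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}
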