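# Streaming FASTQ / gzip-FASTQ readers and writers (4-line dialect) and
# phred decoding.  gzip input is autodetected from the file content (magic
# bytes), never from the file name.

#' Decode a phred quality string
#'
#' @param quality_string ASCII quality string(s).
#' @param offset Phred offset: 33 (Sanger / Illumina 1.8+, default) or 64
#'   (legacy Illumina).
#' @return Integer vector of scores (a list of vectors if several strings
#'   are given).  Any character below the offset raises an error suggesting
#'   the other offset.
#' @export
#' @examples
#' phred_decode("I!") # 40, 0
phred_decode <- function(quality_string, offset = 33) {
  offset <- check_offset(offset)
  dec <- function(s) {
    q <- utf8ToInt(s) - offset
    if (any(q < 0)) {
      stop(sprintf(
        "quality character below phred offset %d; is the file phred+%d encoded?",
        offset, if (offset == 33) 64 else 33
      ), call. = FALSE)
    }
    q
  }
  if (length(quality_string) == 1L) dec(quality_string) else lapply(quality_string, dec)
}

#' Encode integer phred scores as a quality string
#'
#' @param quality Integer scores in `[0, 93]` (offset 33) or `[0, 62]`
#'   (offset 64).
#' @param offset Phred offset, 33 or 64.
#' @return ASCII quality string.
#' @export
phred_encode <- function(quality, offset = 33) {
  offset <- check_offset(offset)
  if (length(quality) == 0L) return("")
  if (any(quality < 0) || any(quality + offset > 126)) {
    stop("phred score not encodable at this offset", call. = FALSE)
  }
  intToUtf8(quality + offset)
}

check_offset <- function(offset) {
  if (!offset %in% c(33, 64)) stop("phred offset must be 33 or 64", call. = FALSE)
  as.integer(offset)
}

#' Is a file gzip-compressed?
#'
#' Checks the two gzip magic bytes (0x1f 0x8b) of the file content; the
#' file name plays no role.
#'
#' @param path File path.
#' @return Logical.
#' @export
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Open a FASTQ file for chunked reading.  gzfile() reads plain text
# transparently as well, so one connection type serves both; is_gzip() is
# still consulted so that unreadable paths fail with context.
open_fastq_reader <- function(path, chunk_records = 10000L) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  is_gzip(path) # also validates readability
  con <- gzfile(path, "rt")
  n_seen <- 0L
  done <- FALSE
  # returns a data.frame of up to chunk_records raw records, or NULL at EOF
  function() {
    if (done) return(NULL)
    lines <- readLines(con, n = 4L * chunk_records)
    if (!length(lines)) {
      done <<- TRUE
      close(con)
      return(NULL)
    }
    if (length(lines) %% 4L != 0L) {
      close(con)
      done <<- TRUE
      stop(sprintf(
        "truncated FASTQ record at record %d in %s",
        n_seen + length(lines) %/% 4L + 1L, path
      ), call. = FALSE)
    }
    i <- seq(1L, length(lines), by = 4L)
    id_lines <- lines[i]
    seqs <- lines[i + 1L]
    plus <- lines[i + 2L]
    quals <- lines[i + 3L]
    bad_at <- !startsWith(id_lines, "@")
    bad_plus <- !startsWith(plus, "+")
    if (any(bad_at) || any(bad_plus)) {
      close(con)
      done <<- TRUE
      stop(sprintf(
        "malformed FASTQ record %d in %s (expected '@'/'+' header lines; multi-line FASTQ is not supported)",
        n_seen + which(bad_at | bad_plus)[1L], path
      ), call. = FALSE)
    }
    ids <- sub("^@", "", id_lines)
    mism <- nchar(seqs) != nchar(quals)
    if (any(mism)) {
      close(con)
      done <<- TRUE
      stop(sprintf(
        "sequence/quality length mismatch for record '%s' in %s",
        ids[which(mism)[1L]], path
      ), call. = FALSE)
    }
    n_seen <<- n_seen + length(ids)
    if (length(lines) < 4L * chunk_records) {
      done <<- TRUE
      close(con)
    }
    data.frame(
      id = ids, sequence = seqs, quality = quals,
      stringsAsFactors = FALSE
    )
  }
}

#' Read a FASTQ file
#'
#' Reads a plain or gzip-compressed 4-line FASTQ file into a data frame.
#' For constant-memory processing of large files use [trim_fastq()], which
#' streams in chunks through the same parser.
#'
#' @param path FASTQ or FASTQ.gz file (compression autodetected from the
#'   content).
#' @param offset Phred offset used for validation-time decoding, 33 or 64.
#' @return A data.frame with character columns `id`, `sequence`, `quality`
#'   (the raw quality string).  Decode scores with [phred_decode()].
#' @export
read_fastq <- function(path, offset = 33) {
  reader <- open_fastq_reader(path)
  chunks <- list()
  while (!is.null(chunk <- reader())) {
    phred_decode(chunk$quality, offset) # validates encoding
    chunks[[length(chunks) + 1L]] <- chunk
  }
  if (!length(chunks)) {
    return(data.frame(
      id = character(0), sequence = character(0),
      quality = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, chunks)
}

#' Write records to a FASTQ file
#'
#' Writes the 4-line dialect; the third line is always a bare `+` (any
#' original `+` line content is not preserved).
#'
#' @param records data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @param gzip Write gzip-compressed output.  Default `NA`: compress when
#'   the path ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, gzip = NA) {
  if (is.na(gzip)) gzip <- grepl("\\.gz$", path)
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    writeLines(as.vector(rbind(
      paste0("@", records$id), records$sequence, "+", records$quality
    )), con)
  }
  invisible(path)
}

# Chunked synchronized iteration over two FASTQ files.  Both readers are
# advanced with the same chunk size; a shortfall on either side is a
# synchronization error reported at the first missing record index.
open_paired_reader <- function(path1, path2, chunk_records = 10000L) {
  r1 <- open_fastq_reader(path1, chunk_records)
  r2 <- open_fastq_reader(path2, chunk_records)
  n_seen <- 0L
  function() {
    c1 <- r1()
    c2 <- r2()
    n1 <- if (is.null(c1)) 0L else nrow(c1)
    n2 <- if (is.null(c2)) 0L else nrow(c2)
    if (n1 != n2) {
      stop(sprintf(
        "paired FASTQ files out of sync: no mate for record %d of %s",
        n_seen + min(n1, n2) + 1L,
        if (n1 > n2) path1 else path2
      ), call. = FALSE)
    }
    if (n1 == 0L) return(NULL)
    n_seen <<- n_seen + n1
    list(r1 = c1, r2 = c2)
  }
}
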