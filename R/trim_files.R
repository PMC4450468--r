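# File-level trimming: wires the per-read estimator to FASTQ streams,
# with paired-end synchronization, min-length filtering and an optional
# poly-N pass.

# trim one chunk of records; returns the records data.frame with trimmed
# sequence/quality plus a 'kept' column
trim_chunk <- function(records, curve, polyN, polyN_first, min_length,
                       offset, threads) {
  one <- function(i) {
    s <- records$sequence[i]
    q <- phred_decode(records$quality[i], offset)
    if (!nchar(s)) {
      return(list(kept = FALSE, sequence = "", quality = integer(0)))
    }
    if (!is.null(polyN) && polyN_first) {
      tr <- trim_read(s, q, polyN = polyN, curve = curve)
      s <- tr$sequence
      q <- tr$quality
      if (!nchar(s)) return(list(kept = FALSE, sequence = "", quality = q))
    }
    tr <- trim_read(s, q, curve = curve)
    s <- tr$sequence
    q <- tr$quality
    if (!is.null(polyN) && !polyN_first && nchar(s)) {
      tr <- trim_read(s, q, polyN = polyN, curve = curve)
      s <- tr$sequence
      q <- tr$quality
    }
    list(kept = nchar(s) >= min_length, sequence = s, quality = q)
  }
  idx <- seq_len(nrow(records))
  res <- if (threads > 1L) {
    parallel::mclapply(idx, one, mc.cores = threads)
  } else {
    lapply(idx, one)
  }
  records$sequence <- vapply(res, `[[`, "", "sequence")
  records$quality <- vapply(
    res, function(r) phred_encode(r$quality, offset), ""
  )
  records$kept <- vapply(res, `[[`, TRUE, "kept")
  records
}

new_counter <- function() list(reads_in = 0L, reads_out = 0L, nt_in = 0, nt_out = 0)

update_counter <- function(cnt, nt_in_chunk, out_records) {
  cnt$reads_in <- cnt$reads_in + length(nt_in_chunk)
  cnt$nt_in <- cnt$nt_in + sum(nt_in_chunk)
  cnt$reads_out <- cnt$reads_out + nrow(out_records)
  cnt$nt_out <- cnt$nt_out + sum(nchar(out_records$sequence))
  cnt
}

#' Trim a FASTQ file (or a synchronized pair)
#'
#' Streams reads through the maximum-likelihood trimmer: each read keeps
#' its best informative segment under threshold `t` (optionally after, or
#' before, a poly-N homopolymer pass), and reads whose retained segment is
#' shorter than `min_read_size` are dropped.  For paired data the two
#' files are processed in lock-step and a pair is dropped whenever either
#' mate is dropped, so the outputs stay synchronized.  Output order equals
#' input order for any `threads` value.
#'
#' @param in1 Input FASTQ(.gz) for the first (or only) end.
#' @param out1 Output path for the first end (gzip if it ends in `.gz`, or
#'   see `gzip`).
#' @param t Minimal phred score considered informative.
#' @param in2,out2 Optional second-end input/output (both or neither).
#' @param polyN Optional homopolymer letter (A/C/G/T/U) to also trim
#'   poly-N runs.
#' @param polyN_first When both passes run, do the poly-N pass before the
#'   quality pass (default) or after.
#' @param min_read_size Minimal retained length to keep a read (default 1).
#' @param offset Phred offset of the input, 33 or 64.
#' @param gzip Compress outputs; default `NA` = decide per output file
#'   name.
#' @param threads Number of worker processes for per-read trimming; the
#'   output is byte-identical for any value.
#' @param chunk_size Records per streamed chunk (memory/throughput
#'   trade-off).
#' @param verbose Print the summary to stderr.
#' @param json_report Optional path: write the summary as JSON.
#' @return An object of class `"trim_report"`: reads/nucleotides in and
#'   out, per end.
#' @export
trim_fastq <- function(in1, out1, t = 20, in2 = NULL, out2 = NULL,
                       polyN = NULL, polyN_first = TRUE, min_read_size = 1,
                       offset = 33, gzip = NA, threads = 1,
                       chunk_size = 10000L, verbose = FALSE,
                       json_report = NULL) {
  if (t <= 0) stop("threshold t must be > 0", call. = FALSE)
  if (min_read_size < 1) stop("min_read_size must be >= 1", call. = FALSE)
  if (is.null(in2) != is.null(out2)) {
    stop("paired input requires paired output (give both in2 and out2)",
      call. = FALSE
    )
  }
  offset <- check_offset(offset)
  if (!is.null(polyN)) polyN <- check_polyN_letter(polyN)
  threads <- max(1L, as.integer(threads))
  curve <- build_curve(t)
  paired <- !is.null(in2)
  c1 <- new_counter()
  c2 <- new_counter()

  append1 <- FALSE
  append2 <- FALSE
  gz1 <- if (is.na(gzip)) grepl("\\.gz$", out1) else gzip
  gz2 <- if (paired && is.na(gzip)) grepl("\\.gz$", out2) else gzip
  emit <- function(records, path, gz, append) {
    con <- (if (gz) gzfile else file)(path, if (append) "at" else "wt")
    on.exit(close(con))
    if (nrow(records)) {
      writeLines(as.vector(rbind(
        paste0("@", records$id), records$sequence, "+", records$quality
      )), con)
    }
  }

  if (!paired) {
    reader <- open_fastq_reader(in1, chunk_size)
    while (!is.null(chunk <- reader())) {
      nt_in <- nchar(chunk$sequence)
      res <- trim_chunk(
        chunk, curve, polyN, polyN_first, min_read_size,
        offset, threads
      )
      out <- res[res$kept, c("id", "sequence", "quality")]
      c1 <- update_counter(c1, nt_in, out)
      emit(out, out1, gz1, append1)
      append1 <- TRUE
    }
    if (!append1) emit(empty_records(), out1, gz1, FALSE)
  } else {
    reader <- open_paired_reader(in1, in2, chunk_size)
    while (!is.null(pair <- reader())) {
      nt1 <- nchar(pair$r1$sequence)
      nt2 <- nchar(pair$r2$sequence)
      res1 <- trim_chunk(
        pair$r1, curve, polyN, polyN_first, min_read_size,
        offset, threads
      )
      res2 <- trim_chunk(
        pair$r2, curve, polyN, polyN_first, min_read_size,
        offset, threads
      )
      keep <- res1$kept & res2$kept # drop the whole pair with either mate
      out_a <- res1[keep, c("id", "sequence", "quality")]
      out_b <- res2[keep, c("id", "sequence", "quality")]
      c1 <- update_counter(c1, nt1, out_a)
      c2 <- update_counter(c2, nt2, out_b)
      emit(out_a, out1, gz1, append1)
      emit(out_b, out2, gz2, append2)
      append1 <- TRUE
      append2 <- TRUE
    }
    if (!append1) {
      emit(empty_records(), out1, gz1, FALSE)
      emit(empty_records(), out2, gz2, FALSE)
    }
  }

  report <- structure(
    list(
      t = t, polyN = polyN, min_read_size = min_read_size,
      paired = paired,
      ends = if (paired) {
        list(end1 = c1, end2 = c2)
      } else {
        list(end1 = c1)
      }
    ),
    class = "trim_report"
  )
  if (!is.null(json_report)) {
    jsonlite::write_json(unclass(report), json_report, auto_unbox = TRUE)
  }
  if (verbose) print_report(report, file = stderr())
  report
}

empty_records <- function() {
  data.frame(
    id = character(0), sequence = character(0), quality = character(0),
    stringsAsFactors = FALSE
  )
}

print_report <- function(x, file = stdout()) {
  for (nm in names(x$ends)) {
    e <- x$ends[[nm]]
    cat(sprintf(
      "%s: reads %d -> %d, nucleotides %.0f -> %.0f (%.1f%% nt removed)\n",
      nm, e$reads_in, e$reads_out, e$nt_in, e$nt_out,
      if (e$nt_in > 0) 100 * (1 - e$nt_out / e$nt_in) else 0
    ), file = file)
  }
  invisible(x)
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf(
    "FASTQ trimming report (t = %g%s, min length %d)\n", x$t,
    if (is.null(x$polyN)) "" else paste0(", poly-", x$polyN),
    x$min_read_size
  ))
  print_report(x)
  invisible(x)
}
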