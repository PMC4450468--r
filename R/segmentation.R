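# Maximum-likelihood double binary segmentation of a read into
# head-unreliable / informative / tail-unreliable segments.

#' IUPAC nucleotide alphabet
#'
#' The standard IUB/IUPAC nucleotide dictionary, including U and the
#' ambiguity codes.  Nucleotide frequencies Pr(N) are estimated over this
#' alphabet; each ambiguity code counts as its own symbol.
#' @export
IUPAC_ALPHABET <- c(
  "A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
  "B", "D", "H", "V", "N"
)

# Floor applied to every probability factor inside log-likelihoods; keeps
# the arithmetic finite and cannot change an argmax except between
# exact-zero candidates.
P_FLOOR <- 1e-30

# normalize a sequence given as one string or a character vector into an
# upper-case character vector, validated against the IUPAC alphabet
seq_chars <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) != 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  sequence <- toupper(sequence)
  bad <- !(sequence %in% IUPAC_ALPHABET)
  if (any(bad)) {
    stop(
      "nucleotide(s) not in the IUPAC alphabet: ",
      paste(unique(sequence[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  sequence
}

check_read <- function(chars, quality) {
  if (length(chars) != length(quality)) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  if (length(quality) && any(quality < 0 | quality > 93)) {
    stop("phred scores must lie in [0, 93]", call. = FALSE)
  }
}

#' Empirical nucleotide frequencies of a segment
#'
#' `Pr(N) = (# of N in the segment) / (segment length)` over the IUPAC
#' alphabet — the closed-form maximum-likelihood estimate of the
#' informative-segment composition for a candidate cut.
#'
#' @param sequence Segment as one string or a character vector.
#' @return Named numeric vector over [IUPAC_ALPHABET], summing to 1.
#' @export
nucleotide_profile <- function(sequence) {
  chars <- seq_chars(sequence)
  if (!length(chars)) stop("empty segment has no profile", call. = FALSE)
  counts <- tabulate(match(chars, IUPAC_ALPHABET), nbins = length(IUPAC_ALPHABET))
  stats::setNames(counts / length(chars), IUPAC_ALPHABET)
}

#' Informative-segment emission probability
#'
#' Probability that a nucleotide belongs to the informative segment:
#' `p(q, t) * Pr(n)`, with `Pr(n)` the empirical frequency of the
#' nucleotide in the candidate segment.  Floored at 1e-30.
#'
#' @param n Nucleotide (IUPAC letter).
#' @param q Phred score.
#' @param profile Named frequency vector from [nucleotide_profile()].
#' @param curve A [build_curve()] object.
#' @return Probability, vectorized over `n`/`q`.
#' @export
f0 <- function(n, q, profile, curve) {
  n <- seq_chars(n)
  pmax(curve_prob(curve, q) * unname(profile[n]), P_FLOOR)
}

#' Unreliable-segment emission probability (quality model)
#'
#' Probability that a nucleotide belongs to an unreliable segment:
#' `(1 - p(q, t)) / 4` — any of the four bases is equally likely where the
#' call carries no information.  Floored at 1e-30.
#'
#' @param q Phred score(s).
#' @param curve A [build_curve()] object.
#' @return Probability, vectorized over `q`.
#' @export
f1_quality <- function(q, curve) {
  pmax((1 - curve_prob(curve, q)) / 4, P_FLOOR)
}

#' Unreliable-segment emission probability (homopolymer model)
#'
#' Letter-aware variant for poly-N trimming: the run letter itself is
#' emitted with probability `p(q, t)` (a correctly called homopolymer
#' base), any other base with `(1 - p(q, t)) / 4` (a miscall that could
#' have been the letter).  Floored at 1e-30.
#'
#' @param n Nucleotide(s) observed.
#' @param q Phred score(s).
#' @param letter Homopolymer letter, one of A, C, G, T, U.
#' @param curve A [build_curve()] object.
#' @return Probability, vectorized over `n`/`q`.
#' @export
f1_polyN <- function(n, q, letter, curve) {
  letter <- check_polyN_letter(letter)
  n <- seq_chars(n)
  p <- curve_prob(curve, q)
  pmax(ifelse(n == letter, p, (1 - p) / 4), P_FLOOR)
}

check_polyN_letter <- function(letter) {
  letter <- toupper(letter)
  if (length(letter) != 1L || !(letter %in% c("A", "C", "G", "T", "U"))) {
    stop("poly-N letter must be one of A, C, G, T, U", call. = FALSE)
  }
  letter
}

# per-position unreliable-segment log-probabilities for a whole read
f1_log_vector <- function(chars, quality, curve, polyN = NULL) {
  if (is.null(polyN)) {
    log(f1_quality(quality, curve))
  } else {
    log(f1_polyN(chars, quality, polyN, curve))
  }
}

#' Log-likelihood of one candidate tail cut-point
#'
#' For a cut at position `k` (1-based, inclusive end of the informative
#' segment): each position `i <= k` contributes `log f0(n_i) - log k` with
#' the nucleotide profile estimated on `[1, k]`, and each position `i > k`
#' contributes `log f1(n_i) - log(m - k)`; an empty tail contributes
#' nothing.  The `1/k` and `1/(m-k)` factors normalize per occupied
#' position of each segment.
#'
#' @param sequence Read sequence (string or character vector).
#' @param quality Integer phred scores, same length.
#' @param k Candidate cut, `1 <= k <= m`.
#' @param curve A [build_curve()] object.
#' @param polyN `NULL` for the quality model, or a homopolymer letter to
#'   use the poly-N unreliable-segment model.
#' @return Finite log-likelihood (probability factors floored at 1e-30).
#' @export
loglik_at_cut <- function(sequence, quality, k, curve, polyN = NULL) {
  chars <- seq_chars(sequence)
  check_read(chars, quality)
  m <- length(chars)
  if (k < 1 || k > m) stop("cut-point k outside [1, m]", call. = FALSE)
  profile <- nucleotide_profile(chars[1:k])
  head <- sum(log(f0(chars[1:k], quality[1:k], profile, curve))) - k * log(k)
  tail <- 0
  if (k < m) {
    i <- (k + 1L):m
    tail <- sum(f1_log_vector(chars[i], quality[i], curve, polyN)) -
      (m - k) * log(m - k)
  }
  head + tail
}

# Numerical tie tolerance for the argmax over cuts: candidates within this
# band of the maximum are treated as tied, so that analytically equal
# likelihoods summed in different orders (e.g. the mirrored head scan vs a
# direct evaluation) resolve identically.
TIE_TOL <- 1e-9

# Core scan: log-likelihood of every cut k in [1, m] for informative-head /
# unreliable-tail, with incremental nucleotide counts.  Ties go to the
# largest k (retain the most nucleotides).
ml_cut_scan <- function(chars, quality, curve, polyN = NULL) {
  m <- length(chars)
  p <- curve_prob(curve, quality)
  f1log <- f1_log_vector(chars, quality, curve, polyN)
  suffix <- rev(cumsum(rev(f1log))) # suffix[i] = sum of f1log[i..m]
  code <- match(chars, IUPAC_ALPHABET)
  counts <- integer(length(IUPAC_ALPHABET))
  ll <- numeric(m)
  for (k in seq_len(m)) {
    counts[code[k]] <- counts[code[k]] + 1L
    idx <- seq_len(k)
    head <- sum(log(pmax(p[idx] * counts[code[idx]] / k, P_FLOOR))) - k * log(k)
    tail <- if (k < m) suffix[k + 1L] - (m - k) * log(m - k) else 0
    ll[k] <- head + tail
  }
  top <- max(ll)
  list(k = max(which(ll >= top - TIE_TOL * (1 + abs(top)))), loglik = ll)
}

#' Estimate the tail cut-point k1
#'
#' Maximum-likelihood cut between an informative head `[1, k1]` and an
#' unreliable tail `(k1, m]`, searched over all `k1` in `[1, m]`.  Ties are
#' broken toward the largest `k1` (keep more nucleotides).
#'
#' @inheritParams loglik_at_cut
#' @return Integer `k1` in `[1, m]`.
#' @export
estimate_tail_cut <- function(sequence, quality, curve, polyN = NULL) {
  chars <- seq_chars(sequence)
  check_read(chars, quality)
  if (!length(chars)) stop("empty read has no cut-point", call. = FALSE)
  ml_cut_scan(chars, quality, curve, polyN)$k
}

#' Estimate the head cut-point k2
#'
#' Given `k1`, the mirrored search on `[1, k1]`: unreliable head
#' `[1, k2 - 1]`, informative segment `[k2, k1]` with its profile estimated
#' on `[k2, k1]`.  Implemented by reversing the subsequence and reusing the
#' tail scan (`k2 = k1 - k1' + 1`); ties therefore resolve to the smallest
#' `k2`.
#'
#' @inheritParams loglik_at_cut
#' @param k1 Tail cut-point from [estimate_tail_cut()].
#' @return Integer `k2` in `[1, k1]`.
#' @export
estimate_head_cut <- function(sequence, quality, k1, curve, polyN = NULL) {
  chars <- seq_chars(sequence)
  check_read(chars, quality)
  if (k1 < 1 || k1 > length(chars)) stop("k1 outside [1, m]", call. = FALSE)
  idx <- k1:1
  k1p <- ml_cut_scan(chars[idx], quality[idx], curve, polyN)$k
  k1 - k1p + 1L
}

#' Segment one read by maximum likelihood
#'
#' Fits the double binary segmentation: the tail cut `k1` is estimated on
#' the whole read first (the longest possible support), then the head cut
#' `k2` on `[1, k1]`.  The retained informative segment is `[k2, k1]`
#' (1-based, inclusive).
#'
#' @param sequence Read sequence (one string or a character vector over the
#'   IUPAC alphabet; case-insensitive).
#' @param quality Integer phred scores, one per nucleotide.
#' @param t Minimal phred score considered informative (default 20).
#'   Ignored when `curve` is supplied.
#' @param polyN `NULL` for quality trimming, or a letter in A/C/G/T/U to
#'   trim homopolymer runs of that letter instead.
#' @param curve Optional pre-built [build_curve()] object.
#' @return An object of class `"read_segmentation"`: the cut-points and the
#'   per-candidate log-likelihood profiles of both scans, with `print`,
#'   `summary`, `coef`, `logLik` and `plot` methods.
#' @export
#' @examples
#' q <- c(rep(2, 5), rep(40, 40), rep(2, 5))
#' s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
#' fit <- segment_read(s, q, t = 20)
#' coef(fit) # k2 = 6, k1 = 45
segment_read <- function(sequence, quality, t = 20, polyN = NULL, curve = NULL) {
  if (is.null(curve)) curve <- build_curve(t)
  chars <- seq_chars(sequence)
  check_read(chars, quality)
  m <- length(chars)
  if (!m) stop("cannot segment an empty read", call. = FALSE)
  tail_scan <- ml_cut_scan(chars, quality, curve, polyN)
  k1 <- tail_scan$k
  idx <- k1:1
  head_scan <- ml_cut_scan(chars[idx], quality[idx], curve, polyN)
  k2 <- k1 - head_scan$k + 1L
  structure(
    list(
      k2 = k2, k1 = k1, m = m, t = curve$t, polyN = polyN,
      loglik_tail = tail_scan$loglik,
      loglik_head = rev(head_scan$loglik), # indexed by k2 in [1, k1]
      sequence = chars, quality = quality
    ),
    class = "read_segmentation"
  )
}

#' @export
coef.read_segmentation <- function(object, ...) {
  c(k2 = object$k2, k1 = object$k1)
}

#' @export
logLik.read_segmentation <- function(object, ...) {
  structure(object$loglik_head[object$k2],
    df = 2L, nobs = object$m, class = "logLik"
  )
}

#' @export
print.read_segmentation <- function(x, ...) {
  cat(sprintf(
    "Read segmentation (t = %g%s): m = %d, retained [%d, %d] (%d nt)\n",
    x$t, if (is.null(x$polyN)) "" else paste0(", poly-", x$polyN),
    x$m, x$k2, x$k1, x$k1 - x$k2 + 1L
  ))
  invisible(x)
}

#' @export
summary.read_segmentation <- function(object, ...) {
  keep <- object$k2:object$k1
  out <- list(
    cut = coef(object), m = object$m, t = object$t, polyN = object$polyN,
    retained = length(keep),
    mean_q_retained = mean(object$quality[keep]),
    mean_q_trimmed = if (length(keep) < object$m) {
      mean(object$quality[-keep])
    } else {
      NA_real_
    },
    logLik = as.numeric(logLik(object))
  )
  class(out) <- "summary.read_segmentation"
  out
}

#' @export
print.summary.read_segmentation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "ML read segmentation (t = %g%s)\n",
      "  read length       : %d\n",
      "  retained segment  : [%d, %d] (%d nt)\n",
      "  mean phred kept   : %.2f\n",
      "  mean phred trimmed: %s\n",
      "  log-likelihood    : %.3f\n"
    ),
    x$t, if (is.null(x$polyN)) "" else paste0(", poly-", x$polyN),
    x$m, x$cut["k2"], x$cut["k1"], x$retained, x$mean_q_retained,
    if (is.na(x$mean_q_trimmed)) "-" else sprintf("%.2f", x$mean_q_trimmed),
    x$logLik
  ))
  invisible(x)
}

#' @export
plot.read_segmentation <- function(x, ...) {
  graphics::plot(seq_len(x$m), x$quality,
    type = "h", xlab = "position",
    ylab = "phred score", main = sprintf("retained [%d, %d]", x$k2, x$k1), ...
  )
  graphics::abline(v = c(x$k2 - 0.5, x$k1 + 0.5), col = 2, lwd = 2)
  graphics::abline(h = x$t, lty = 3)
  invisible(x)
}

#' Trim one read
#'
#' Runs [segment_read()] and extracts the retained informative segment;
#' the read is kept only if that segment has at least `min_length`
#' nucleotides.  A zero-length read is never kept.
#'
#' @inheritParams segment_read
#' @param min_length Minimal retained length to keep the read (default 1).
#' @return A list of class `"trim_result"`: `kept` (logical), `k2`, `k1`,
#'   `sequence` (retained subsequence, string), `quality` (retained
#'   scores).  When `kept` is `FALSE` the sequence is empty and the
#'   cut-points are `NA` for an empty input read.
#' @export
trim_read <- function(sequence, quality, t = 20, min_length = 1,
                      polyN = NULL, curve = NULL) {
  if (min_length < 1) stop("min_length must be >= 1", call. = FALSE)
  chars <- seq_chars(sequence)
  check_read(chars, quality)
  if (!length(chars)) {
    return(structure(
      list(
        kept = FALSE, k2 = NA_integer_, k1 = NA_integer_,
        sequence = "", quality = integer(0)
      ),
      class = "trim_result"
    ))
  }
  fit <- segment_read(chars, quality, t = t, polyN = polyN, curve = curve)
  keep <- fit$k2:fit$k1
  structure(
    list(
      kept = length(keep) >= min_length, k2 = fit$k2, k1 = fit$k1,
      sequence = paste(chars[keep], collapse = ""),
      quality = quality[keep]
    ),
    class = "trim_result"
  )
}

#' Trim a homopolymer run from a read's extremities
#'
#' [trim_read()] with the letter-aware unreliable-segment model
#' ([f1_polyN()]), so runs of `letter` (e.g. a poly-A tail) are trimmed
#' even when their phred scores are moderate.
#'
#' @inheritParams trim_read
#' @param letter Homopolymer letter, one of A, C, G, T, U.
#' @export
trim_polyN <- function(sequence, quality, letter, t = 20, min_length = 1,
                       curve = NULL) {
  trim_read(sequence, quality,
    t = t, min_length = min_length,
    polyN = check_polyN_letter(letter), curve = curve
  )
}

#' @export
print.trim_result <- function(x, ...) {
  if (x$kept) {
    cat(sprintf(
      "Trimmed read: retained [%d, %d], %d nt\n", x$k2, x$k1,
      nchar(x$sequence)
    ))
  } else {
    cat("Trimmed read: discarded (below minimum length)\n")
  }
  invisible(x)
}
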