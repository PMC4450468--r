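# Independent naive oracles for the segmentation likelihood: everything is
# recomputed from scratch per candidate cut (table() counts, explicit
# products in log space), sharing no code with the production scan.

ORACLE_ALPHABET <- c(
  "A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
  "B", "D", "H", "V", "N"
)

oracle_f1 <- function(chars, p, polyN) {
  if (is.null(polyN)) (1 - p) / 4 else ifelse(chars == polyN, p, (1 - p) / 4)
}

oracle_loglik <- function(chars, qual, k, curve, polyN = NULL) {
  m <- length(chars)
  p <- curve_prob(curve, qual)
  tab <- table(factor(chars[1:k], levels = ORACLE_ALPHABET))
  pr <- as.numeric(tab[chars[1:k]]) / k
  ll <- sum(log(pmax(p[1:k] * pr, 1e-30))) - k * log(k)
  if (k < m) {
    i <- (k + 1):m
    f1 <- oracle_f1(chars[i], p[i], polyN)
    ll <- ll + sum(log(pmax(f1, 1e-30))) - (m - k) * log(m - k)
  }
  ll
}

# same tie convention as the production scan: near-equal log-likelihoods
# (analytic ties summed in a different order) count as tied
oracle_ties <- function(ll) ll >= max(ll) - 1e-9 * (1 + abs(max(ll)))

# exhaustive argmax over k in [1, m]; ties to the largest k
oracle_k1 <- function(chars, qual, curve, polyN = NULL) {
  ll <- vapply(
    seq_along(chars),
    function(k) oracle_loglik(chars, qual, k, curve, polyN), 0
  )
  max(which(oracle_ties(ll)))
}

# direct head formulation (no mirroring): f1 on [1, k2-1], f0 on [k2, k1]
# with the profile estimated on [k2, k1]; ties to the smallest k2
oracle_k2_direct <- function(chars, qual, k1, curve, polyN = NULL) {
  p <- curve_prob(curve, qual)
  ll <- vapply(1:k1, function(k2) {
    seg <- k2:k1
    len <- length(seg)
    tab <- table(factor(chars[seg], levels = ORACLE_ALPHABET))
    pr <- as.numeric(tab[chars[seg]]) / len
    v <- sum(log(pmax(p[seg] * pr, 1e-30))) - len * log(len)
    if (k2 > 1) {
      i <- 1:(k2 - 1)
      f1 <- oracle_f1(chars[i], p[i], polyN)
      v <- v + sum(log(pmax(f1, 1e-30))) - (k2 - 1) * log(k2 - 1)
    }
    v
  }, 0)
  min(which(oracle_ties(ll)))
}

# independent cubic Bezier evaluation by de Casteljau recursion
decasteljau <- function(u, pts) {
  while (length(pts) > 1) {
    pts <- (1 - u) * pts[-length(pts)] + u * pts[-1]
  }
  pts
}

random_read <- function(m, q_max = 45, with_n = TRUE) {
  letters <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else NULL
  list(
    chars = sample(letters, m, replace = TRUE, prob = prob),
    qual = sample(0:q_max, m, replace = TRUE)
  )
}
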