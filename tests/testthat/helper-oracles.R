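# Independent brute-force oracles used to validate the package's
# implementations. Kept deliberately naive and separate from the code
# paths they check.

# Sequon positions by regular-expression lookahead (vs the package's
# character scan).
oracle_find_sequons <- function(s, allow_proline = FALSE) {
  pat <- if (allow_proline) "N(?=.[ST])" else "N(?=[^P][ST])"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Missed cleavages by explicit position loop.
oracle_missed_cleavages <- function(s) {
  chars <- strsplit(s, "")[[1]]
  count <- 0L
  for (i in seq_len(length(chars) - 1L)) {
    if (chars[i] %in% c("K", "R") && chars[i + 1L] != "P") count <- count + 1L
  }
  count
}

# AUC by exhaustive pairwise concordance counting.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# DeLong variance of the AUC difference by direct enumeration of the
# structural components V10/V01 and their sample covariances.
oracle_delong_var <- function(sa, sb, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  comp <- function(s) {
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + psi(s[pos[i]], s[neg[j]])
      v10[i] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + psi(s[neg[j]], s[pos[i]])
      v01[j] <- acc / m
    }
    list(v10 = v10, v01 = v01, theta = mean(v10))
  }
  ca <- comp(sa); cb <- comp(sb)
  sc <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  (sc(ca$v10, ca$v10) - 2 * sc(ca$v10, cb$v10) + sc(cb$v10, cb$v10)) / m +
    (sc(ca$v01, ca$v01) - 2 * sc(ca$v01, cb$v01) + sc(cb$v01, cb$v01)) / n
}

# Majority class by literal counting.
oracle_majority <- function(votes, positive) {
  n_pos <- sum(votes == positive)
  n_neg <- length(votes) - n_pos
  if (n_pos >= n_neg) positive else setdiff(unique(votes), positive)[1]
}
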