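# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# Brute-force digestion: enumerate every substring, keep those whose
# boundaries are valid cleavage sites and whose internal missed-cleavage
# count is within bounds.
oracle_digest <- function(sequence, enzyme_rule, max_missed, min_len,
                          max_len = Inf) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_site <- function(pos) {          # cleavage after position pos (1-based)
    if (pos < 1 || pos >= n) return(FALSE)
    if (!(chars[pos] %in% c("K", "R"))) return(FALSE)
    if (enzyme_rule == "trypsin_blocked_by_proline" && chars[pos + 1L] == "P") {
      return(FALSE)
    }
    TRUE
  }
  out <- data.frame(peptide = character(0), missed = integer(0),
                    start = integer(0))
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      start_ok <- (i == 1L) || is_site(i - 1L)
      end_ok <- (j == n) || is_site(j)
      if (!start_ok || !end_ok) next
      internal <- if (j > i) sum(vapply(i:(j - 1L), is_site, TRUE)) else 0L
      if (internal > max_missed) next
      out <- rbind(out, data.frame(peptide = paste(chars[i:j], collapse = ""),
                                   missed = internal, start = i - 1L))
    }
  }
  out[order(out$start, out$start + nchar(out$peptide)), , drop = FALSE]
}

random_aa_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Direct-formula moderated t: moment equations on log s^2, trigamma
# inversion by uniroot (a different numerical route than the package's
# Newton iteration).
oracle_modt <- function(x, a_cols, b_cols) {
  na <- length(a_cols); nb <- length(b_cols)
  d <- na + nb - 2
  ma <- rowMeans(x[, a_cols, drop = FALSE])
  mb <- rowMeans(x[, b_cols, drop = FALSE])
  s2 <- (rowSums((x[, a_cols, drop = FALSE] - ma)^2) +
           rowSums((x[, b_cols, drop = FALSE] - mb)^2)) / d
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    half_d0 <- uniroot(function(u) trigamma(u) - evar,
                       lower = 1e-8, upper = 1e8, tol = 1e-14)$root
    d0 <- 2 * half_d0
    s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
    s2_post <- rep(s0_2, length(s2))
  }
  fc <- ma - mb
  tstat <- fc / sqrt(s2_post * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = d + d0)
  list(d0 = d0, s0_2 = s0_2, t = tstat, p = p, log2fc = fc)
}

# Closed-form Pearson chi-square for a 2x2 table.
oracle_chisq_2x2 <- function(a, b, cc, d) {
  n <- a + b + cc + d
  stat <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

load_modt_fixture <- function() {
  path <- system.file("extdata", "modt_fixture.tsv", package = "crossdia")
  read_matrix_tsv(path, scale = "log2")
}
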