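# Independent brute-force oracles, deliberately separate from the package's
# implementation paths.

# Exact two-sided Mann-Whitney p by enumeration of all rank splits
# (no-ties case). Mirrors the doubled-smaller-tail convention.
mw_exact_oracle <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  splits <- utils::combn(n + m, n)
  w_all <- colSums(matrix(seq_len(n + m)[splits], nrow = n))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Holm step-down straight from its definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Standard genetic code, written out independently of Biostrings.
codon_table_oracle <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # first base slowest, third fastest, matching the string layout above
  codons <- unlist(lapply(bases, function(b1)
    unlist(lapply(bases, function(b2) paste0(b1, b2, bases)))))
  stats::setNames(aa, codons)
}

# Frame-0 translation of insert+tail up to the first stop.
translate_oracle <- function(insert, tail) {
  tab <- codon_table_oracle()
  s <- paste0(insert, tail)
  out <- character(0)
  i <- 1
  while (i + 2 <= nchar(s)) {
    a <- tab[[substr(s, i, i + 2)]]
    if (a == "*") return(paste(out, collapse = ""))
    out <- c(out, a)
    i <- i + 3
  }
  stop("oracle: ran out of sequence without a stop")
}

# Longest hydrophobic run by checking every substring.
max_run_oracle <- function(p, set) {
  n <- nchar(p)
  best <- 0L
  chars <- strsplit(p, "")[[1]]
  for (i in seq_len(n)) for (j in i:n) {
    if (all(chars[i:j] %in% set)) best <- max(best, j - i + 1L)
  }
  best
}

# Upper-tail F probability by numerical integration of the density.
f_pvalue_oracle <- function(f, df1, df2) {
  if (f <= 0) return(1)
  stats::integrate(function(x) stats::df(x, df1, df2), f, Inf,
                   rel.tol = 1e-10)$value
}

# Random peptide over the standard alphabet.
random_peptide <- function(n) {
  paste(sample(names(kd_hydropathy()), n, replace = TRUE), collapse = "")
}

# Printed tester-set properties (id, length, GRAVY) used as fixtures.
tester_printed <- function() {
  tibble::tribble(
    ~id, ~length, ~gravy,
    "CL1", 16L, 0.569, "10-1", 28L, 0.268, "10-6", 39L, 0.010,
    "10-13", 17L, 0.212, "10-15", 7L, 0.429, "10-21", 26L, 0.288,
    "10-31", 33L, 0.533, "10-34", 7L, 3.943, "10-40", 21L, 0.829,
    "10-43", 22L, -0.586, "12-32", 18L, 0.650, "12-33", 34L, 0.241,
    "12-86", 19L, 1.126, "12-98", 33L, 0.664
  )
}
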