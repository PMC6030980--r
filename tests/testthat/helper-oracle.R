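# Independent mass oracle for the test suite.
#
# Residue monoisotopic masses frozen from an independent implementation
# (pyteomics 5.0.1 std_aa_mass), NOT computed from the package's own
# element tables. All oracle arithmetic below uses only these constants.

ORACLE_RESIDUE_MASS <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)
ORACLE_WATER   <- 18.0105646837
ORACLE_AMMONIA <- 17.0265491010
ORACLE_PROTON  <- 1.00727646677
ORACLE_H       <- 1.0078250319

# Neutral peptide mass from a plain residue string plus mod mass deltas.
oracle_peptide_mass <- function(seq, mod_deltas = 0) {
  chars <- strsplit(seq, "")[[1]]
  sum(ORACLE_RESIDUE_MASS[chars]) + ORACLE_WATER + sum(mod_deltas)
}

# Neutral fragment masses for a linear unmodified peptide string.
oracle_b <- function(seq, i) {
  sum(ORACLE_RESIDUE_MASS[strsplit(seq, "")[[1]][1:i]])
}
oracle_y <- function(seq, j) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  sum(ORACLE_RESIDUE_MASS[chars[(n - j + 1):n]]) + ORACLE_WATER
}
oracle_mz <- function(neutral, z) (neutral + z * ORACLE_PROTON) / z

# Brute-force all-pairs closest-within-tolerance matcher: for every
# fragment, scan every peak, keep the closest peak within tolerance.
# Deliberately O(peaks x fragments); ties break toward the lower m/z peak
# (scan order is ascending m/z).
oracle_match <- function(peak_mz, frag_mz, tol_value, tol_unit = "ppm") {
  out <- integer(length(frag_mz))
  for (f in seq_along(frag_mz)) {
    win <- if (tol_unit == "ppm") tol_value * frag_mz[f] / 1e6 else tol_value
    best <- NA_integer_
    best_d <- Inf
    for (p in seq_along(peak_mz)) {
      d <- abs(peak_mz[p] - frag_mz[f])
      if (d <= win && d < best_d) {
        best <- p
        best_d <- d
      }
    }
    out[f] <- best
  }
  out
}

random_peptide <- function(len, exclude = character()) {
  aa <- setdiff(names(ORACLE_RESIDUE_MASS), exclude)
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
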