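# Five-factor biophysicochemical solution of Atchley et al. (2005, PNAS
# 102:6395-6400), Table 2. Factors: f1 polarity/hydrophobicity, f2 secondary
# structure propensity, f3 molecular size/mass, f4 codon degeneracy/amino acid
# composition, f5 electrostatic charge. Frozen constants; part of the package's
# test fixtures.
.atchley_values <- matrix(c(
  # f1      f2      f3      f4      f5
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, byrow = TRUE,
dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                paste0("f", 1:5)))

#' Atchley five-factor table
#'
#' Returns the fixed 20 x 5 matrix of Atchley factors used to encode CDR3beta
#' 4-mers: polarity/hydrophobicity, secondary-structure propensity, size/mass,
#' codon degeneracy and electrostatic charge, one row per canonical amino acid.
#'
#' @return Numeric matrix with amino-acid rownames and columns `f1`..`f5`.
#' @export
#' @examples
#' atchley_table()["A", ]
atchley_table <- function() .atchley_values

# Largest five-factor Manhattan distance between any two amino acids,
# brute-forced over all pairs. Because positions contribute independently, the
# largest 4-mer distance is 4x this pair maximum; that constant normalizes
# kmer distances to [0, 1] with 1 attainable.
.max_pair_manhattan <- local({
  d <- as.matrix(stats::dist(.atchley_values, method = "manhattan"))
  max(d)
})

#' Normalizing constants for the 4-mer Manhattan distance
#'
#' The default normalizer (`"pair_max"`) is the largest Manhattan distance any
#' pair of 4-mers can achieve: four times the largest five-factor Manhattan
#' distance between two amino acids. The `"dimension_range"` alternative sums
#' the per-dimension (max - min) spreads over the 20 encoded dimensions; it is
#' larger, so no realizable pair attains distance 1 under it.
#'
#' @param method One of `"pair_max"` (default) or `"dimension_range"`.
#' @return A positive scalar.
#' @export
kmer_dmax <- function(method = c("pair_max", "dimension_range")) {
  method <- match.arg(method)
  if (method == "pair_max") {
    4 * .max_pair_manhattan
  } else {
    rng <- apply(.atchley_values, 2, range)
    4 * sum(rng[2, ] - rng[1, ])
  }
}
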