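# Independent oracles, deliberately written without the package's own
# computational paths.

# Hand-arithmetic correction oracle for a small community: direct
# evaluation of the frequency -> cell-fraction -> biovolume-fraction
# formulas with scalar arithmetic.
oracleCorrect <- function(fr, volumes, a = 9.58, b = 0.66) {
  rc <- a * volumes^b
  fr <- fr / sum(fr)
  w <- fr / rc
  fc <- w / sum(w)
  fv <- fc * volumes / sum(fc * volumes)
  list(rc = rc, fc = fc, fv = fv)
}

# Exact-arithmetic normal equations for the OLS line v ~ u on small
# integer inputs: slope and intercept as ratios of integers, computed
# without floating-point cancellation (all intermediates are integers,
# exactly representable for the small test cases used).
oracleIntegerLine <- function(u, v) {
  stopifnot(all(u == round(u)), all(v == round(v)))
  n <- length(u)
  su <- sum(u); sv <- sum(v); suv <- sum(u * v); suu <- sum(u * u)
  num <- n * suv - su * sv        # integer
  den <- n * suu - su * su        # integer
  slope <- num / den
  intercept <- (sv * den - num * su) / (n * den)
  list(slope = slope, intercept = intercept)
}

# Delta-method standard error of the cell fractions under multinomial
# sampling of the read frequencies at a given depth.
oracleFcSE <- function(p, rc, depth) {
  w <- 1 / rc
  S <- sum(w * p)
  vapply(seq_along(p), function(i) {
    g <- -w[i] * p[i] * w / S^2
    g[i] <- g[i] + w[i] / S
    sqrt((sum(g^2 * p) - sum(g * p)^2) / depth)
  }, numeric(1))
}

# A small trait table exercising ranges, shape-derived volumes and the
# trait derivations; written to 'path' as CSV.
writeFixtureTraits <- function(path) {
  writeLines(c(
    "taxon_id,domain,shape,dim1,dim2,volume_um3,rrn_per_genome,ploidy,rrn_per_cell,genome_mbp,dna_per_cell_mbp",
    "cocci_sp,bacteria,sphere,1,,,2,4,,4,16",
    paste0("rod_sp,bacteria,capsule,0.5,2,,1,,,2.5,7.5"),
    "range_sp,archaea,,,,10–20,2,212.5,,,",
    "euk_sp,eukaryote,,,,1000,,,5000,,"
  ), path, useBytes = TRUE)
  path
}
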