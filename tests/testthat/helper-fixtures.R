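# Shared fixture builders and independent oracles.  Oracles here are written
# from first principles (their own constants, brute-force loops) so they stay
# independent of the code paths they check.

# independent physical constants (CODATA), assembled separately from the
# package's internal table
ORACLE <- local({
  e <- 1.602176634e-19; NAv <- 6.02214076e23
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  list(
    coulomb_k = e^2 * NAv / (4 * pi * eps0 * 1e-10 * 4184),  # kcal*A/(mol*e^2)
    kappa = function(I, eps, T) {
      if (I == 0) return(0)
      sqrt(2 * NAv * e^2 * I * 1000 / (eps0 * eps * kB * T)) * 1e-10
    })
})

# finite-size-ion Debye-Hueckel potential (exclusion radius b), kcal/mol/e
oracle_dh <- function(r, q, eps, kappa, b) {
  ifelse(r >= b,
         q * ORACLE$coulomb_k * exp(-kappa * (r - b)) / (eps * (1 + kappa * b) * r),
         q * ORACLE$coulomb_k / (eps * r) -
           q * ORACLE$coulomb_k / (eps * b) +
           q * ORACLE$coulomb_k / (eps * (1 + kappa * b) * b))
}

# a bare ion "structure" row
ion_structure <- function(q = -1, radius = 2, pos = c(0, 0, 0), role = "P1") {
  tibble::tibble(atom = "ION", role = role, lipid = 1L, leaflet = 1L,
                 is_phosphate = TRUE, x = pos[1], y = pos[2], z = pos[3],
                 charge = q, radius = radius)
}

random_grid <- function(dims = c(4, 4, 4), spacing = 1, origin = c(0, 0, 0),
                        label = "", f32 = TRUE) {
  v <- array(rnorm(prod(dims)), dims)
  if (f32) v <- array(memesp:::f32(v), dims)
  potential_grid(v, spacing, origin, label = label)
}

const_grid <- function(value, dims = c(4, 4, 4), spacing = 1,
                       origin = c(0, 0, 0)) {
  potential_grid(array(value, dims), spacing, origin)
}

# brute-force weighted median with the lower/midpoint rule
oracle_weighted_median <- function(v, w) {
  o <- order(v); v <- v[o]; w <- w[o]
  cw <- cumsum(w); W <- sum(w)
  j <- which(cw >= W / 2)[1]
  if (cw[j] == W / 2) (v[j] + v[j + 1]) / 2 else v[j]
}

# brute-force nested median (b groups of b of b, in arrival order)
oracle_nested_median <- function(s, b = 9) {
  m1 <- vapply(seq_len(b^2),
               function(g) median(s[((g - 1) * b + 1):(g * b)]), numeric(1))
  m2 <- vapply(seq_len(b),
               function(g) median(m1[((g - 1) * b + 1):(g * b)]), numeric(1))
  median(m2)
}

# minimal independent OpenDX parser (kept deliberately separate from
# read_dx_grid): returns list(dims, origin, spacing, values) with values in
# the package's x-fastest order
naive_dx_parse <- function(lines) {
  g1 <- regmatches(lines, regexec(
    "gridpositions counts\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)", lines))
  hit <- which(lengths(g1) == 4)[1]
  dims <- as.integer(g1[[hit]][2:4])
  org <- as.numeric(strsplit(trimws(sub("origin", "",
    lines[grep("^origin", lines)[1]])), "\\s+")[[1]])
  dl <- lines[grep("^delta", lines)][1]
  spacing <- as.numeric(strsplit(trimws(sub("delta", "", dl)), "\\s+")[[1]])[1]
  i0 <- grep("data follows", lines)[1] + 1
  vals <- numeric(0); i <- i0
  while (length(vals) < prod(dims)) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  arr <- aperm(array(vals[seq_len(prod(dims))], rev(dims)), c(3, 2, 1))
  list(dims = dims, origin = org, spacing = spacing, values = arr)
}
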