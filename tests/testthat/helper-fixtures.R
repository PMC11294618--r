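# shared in-code fixtures; everything is generated, nothing read from disk

# a tiny perfectly balanced two-ion water in meq/L
balanced_ions <- function(meq = 10) {
  data.frame(Na = meq, Cl = meq)
}

# random nonnegative ion vectors (meq/L) for property-style loops
random_ion_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    Ca = runif(n, 0.1, 20), Mg = runif(n, 0.1, 15),
    Na = runif(n, 0.1, 25), K = runif(n, 0.01, 2),
    Cl = runif(n, 0.1, 35), SO4 = runif(n, 0.1, 20),
    HCO3 = runif(n, 0.1, 5), NO3 = runif(n, 0, 1)
  )
}

# the 5 x 3 spreadsheet fixture used by the weighting oracles
weight_fixture <- function() {
  cbind(a = c(1, 2, 3, 4, 5), b = c(2, 2, 3, 5, 9), c = c(10, 8, 6, 4, 2))
}
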