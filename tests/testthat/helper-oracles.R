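# Independent oracles, deliberately coded apart from the package paths
# they check.

# Closed-form simple linear regression via the Sigma formulas.
ols_oracle <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  a <- sum((x - xm) * (y - ym)) / sxx
  b <- ym - a * xm
  ss_res <- sum((y - (a * x + b))^2)
  ss_tot <- sum((y - ym)^2)
  list(a = a, b = b, r2 = 1 - ss_res / ss_tot)
}

# Sackur-Tetrode Gibbs energy of a monoatomic ideal gas at 1 atm,
# evaluated in SI and converted at the end (different arithmetic path
# from the implementation, which works in kcal throughout).
sackur_tetrode_oracle <- function(T, mass_kg = 1.67262192369e-27) {
  R_si <- 8.31446261815324
  kB <- 1.380649e-23; h <- 6.62607015e-34; P <- 101325
  kT <- kB * T
  lambda3 <- (h^2 / (2 * pi * mass_kg * kT))^1.5   # thermal wavelength^3
  S <- R_si * (log(kT / (P * lambda3)) + 2.5)
  (2.5 * R_si * T - T * S) / 4184
}

# RT ln(RT / (1 atm L mol^-1)) in kcal, via SI.
std_state_oracle <- function(T) {
  R_si <- 8.31446261815324
  vm_l <- R_si * T / 101325 * 1000
  R_si * T * log(vm_l) / 4184
}

# Full synthetic pipeline: family -> calibrations -> meta-fit -> g_sol_opt.
recover_g_sol_opt <- function(cfg) {
  fam <- generate_method_family(cfg)
  res <- estimate_proton_energy(fam$table, T = cfg$T)
  res$meta$g_sol_opt
}
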