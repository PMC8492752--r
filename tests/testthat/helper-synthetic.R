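# Shared fixtures: small, fast study configurations built in code.

# compact study: fewer observations/OTUs so pipeline-level tests stay quick
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, traps_per_zone = 2, n_flux_obs = 80,
                   n_otus = 60, library_size = 2000,
                   rarefaction_depth = 1500, ...)
}

# noise-free chemistry (exact forward model)
noisefree_chem_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, isotope_noise_permil = 0,
                   conc_noise_sdlog = 0, ...)
}

# least-squares Procrustes distance after optimal rotation/reflection +
# translation (used to compare ordinations up to rigid motion)
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  sqrt(sum((A - B %*% R)^2))
}
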