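# Shared fixtures: small, fast configurations used across test files.

quietAcq <- function(...) {
  args <- list(...)
  if (is.null(args$artifactRate)) args$artifactRate <- 0
  if (is.null(args$bleachTau)) args$bleachTau <- Inf
  do.call(acquisitionParams, args)
}

# ground-truth ROI block of the default acquisition (siteCenter 32,
# width 12)
defaultSite <- 27:38

# amplitude-level synthetic bouton: amplitudes + noise models per
# condition, bypassing trial rendering (fast input for the fitter)
sampleBouton <- function(truth, n = 300, sigma0 = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- conditionNames(truth)
  amps <- lapply(setNames(nm = conds), function(cc)
    sampleAmplitudes(truth, cc, n, sigma0))
  noise <- lapply(setNames(nm = conds), function(cc) sigma0)
  list(amps = amps, noise = noise)
}

# independent closed-form saturation mapping used as the oracle for
# peak positions (kept deliberately separate from the package routine)
oracleSaturation <- function(k, q, bMax) {
  kd <- bMax / q - 1
  bMax * k / (kd + k)
}
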