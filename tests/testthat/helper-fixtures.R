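# Shared fixtures: deterministic population variants and small utilities.

# Population with all IIV and residual error switched off.
pop_deterministic <- function(pop = default_population()) {
  pop$iiv[] <- 0
  for (obs in names(pop$residual)) {
    pop$residual[[obs]]$prop <- 0
    pop$residual[[obs]]$add <- 0
  }
  pop
}

# Reduced-variability population for fast estimation unit tests.
pop_low_noise <- function(pop = default_population()) {
  pop$iiv[] <- 0.1
  for (obs in names(pop$residual)) {
    pop$residual[[obs]]$prop <- 0.05
    pop$residual[[obs]]$add <- 0
  }
  pop
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# silence flooring messages in stochastic bulk simulations
quiet_sim <- function(expr) {
  op <- options(gcdcaspk.quiet = TRUE)
  on.exit(options(op))
  expr
}
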