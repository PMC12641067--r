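#' Draw one individual's structural parameters
#'
#' Parameters carrying inter-individual variability are drawn log-normally,
#' `theta_i = theta * exp(eta)` with `eta ~ N(0, omega^2)`; parameters
#' without IIV are copied from the typical values. Randomness comes from R's
#' global generator; call `set.seed()` for reproducibility.
#'
#' @param pop A [default_population()]-style object.
#' @return Named numeric vector of realized parameter values
#'   (class `individual_parameters`).
#' @export
sample_individual <- function(pop) {
  m <- .sample_individuals(pop, 1L)
  structure(m[, 1], class = "individual_parameters")
}

# n individuals at once; returns a matrix [n_param x n] with rownames.
.sample_individuals <- function(pop, n) {
  th <- pop$fixed
  out <- matrix(th, length(th), n, dimnames = list(names(th), NULL))
  for (p in names(pop$iiv)) {
    om <- pop$iiv[[p]]
    if (om > 0)
      out[p, ] <- th[[p]] * exp(stats::rnorm(n, 0, om))
  }
  out
}

#' Apply residual unexplained variability to model predictions
#'
#' Combined error model `y = f * (1 + eps_p) + eps_a` with
#' `eps_p ~ N(0, sigma_prop^2)` and `eps_a ~ N(0, sigma_add^2)`. Negative
#' draws are floored at zero (concentrations and amounts are physical
#' quantities); flooring is reported via a message unless
#' `options(gcdcaspk.quiet = TRUE)`.
#'
#' @param prediction Non-negative model predictions (vector).
#' @param observable One of `"biomarker_plasma"`, `"biomarker_urine"`,
#'   `"rifampicin_plasma"`, `"probenecid_plasma"`.
#' @param residual The `residual` element of a population object.
#' @return Simulated observations, same length as `prediction`.
#' @export
apply_residual <- function(prediction, observable, residual) {
  if (!observable %in% names(residual))
    stop("unknown observable: ", observable)
  if (any(prediction < 0)) stop("predictions must be non-negative")
  r <- residual[[observable]]
  y <- prediction * (1 + stats::rnorm(length(prediction), 0, r$prop)) +
    stats::rnorm(length(prediction), 0, r$add)
  nneg <- sum(y < 0)
  if (nneg > 0 && !isTRUE(getOption("gcdcaspk.quiet", FALSE)))
    message(nneg, " simulated ", observable,
            " value(s) below zero floored at 0")
  pmax(y, 0)
}

# Residual variance of one observation given its prediction (internal).
.res_var <- function(f, prop, add) {
  pmax((prop * f)^2 + add^2, 1e-20)
}
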