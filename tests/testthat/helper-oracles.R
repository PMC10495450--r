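# Independent oracles and generators shared across the test files.

# Analytic periodic solution of the RCR pressure ODE for sinusoidal inflow
# Q(t) = Q0 + A sin(w t): integrating-factor solution of the linear
# first-order equation, written with complex phasors, independent of the
# package's time stepper.
analytic_rcr_sinusoid <- function(times, Q0, A, omega, bc) {
  Rp <- bc$proximal_resistance
  Rd <- bc$distal_resistance
  C <- bc$compliance
  lambda <- 1 / (Rd * C)
  H <- ((1 + Rp / Rd) / C + 1i * omega * Rp) / (lambda + 1i * omega)
  bc$distal_pressure + Q0 * (Rp + Rd) + Im(H * A * exp(1i * omega * times))
}

# Random positive lumped elements over physiological magnitude ranges.
rand_elements <- function(n) {
  lapply(seq_len(n), function(i)
    lumped_element(10^stats::runif(1, 6, 10), 10^stats::runif(1, -16, -12)))
}

# A tiny self-consistent synthetic tree packaged as an atlas object: the
# "printed" values are generated from the same physics and recipes the
# package applies, so every check in the discrepancy report must come back
# clean.
synthetic_consistent_atlas <- function() {
  mu <- 0.0035
  d <- c(4e-3, 2e-3, 1e-3)
  l <- c(20e-3, 15e-3, 10e-3)
  r <- 128 * mu * l / (pi * d^4)
  gh <- 2500
  cc <- pi * d^3 * l / (4 * gh)
  rows <- data.frame(
    label = c("B1", "B2", "B3"),
    name = c("trunk", "branch", "twig"),
    diameter = d, length = l,
    multiplicity = c(1, 1, 4),
    group = c("proximal", "ICA-distal", "ICA-distal"),
    printed_resistance = r, printed_compliance = cc,
    alt_length = NA_real_, notes = "",
    stringsAsFactors = FALSE)
  rec_r <- recipe_table(
    reduction_recipe("R1", "parallel", c("B2", "B3"), c(1, 4)),
    reduction_recipe("R2", "series", c("B1", "R1")))
  rec_c <- recipe_table(
    reduction_recipe("C1", "parallel", c("B2", "B3"), c(1, 4)),
    reduction_recipe("C2", "series", c("B1", "C1")))
  base <- stats::setNames(
    mapply(lumped_element, r, cc, SIMPLIFY = FALSE), rows$label)
  ev_r <- evaluate_recipes(rec_r, base)
  ev_c <- evaluate_recipes(rec_c, base)
  printed <- c(
    vapply(ev_r, `[[`, numeric(1), "resistance"),
    vapply(ev_c, `[[`, numeric(1), "compliance"))
  topo <- data.frame(parent = c("B1", "B1"), child = c("B2", "B3"),
                     multiplicity = c(1, 4))
  carotidwk:::new_carotid_atlas(
    rows, list(resistance = rec_r, compliance = rec_c), topo,
    dialect = "self-consistent", printed_intermediates = printed,
    viscosity_candidates = mu)
}
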