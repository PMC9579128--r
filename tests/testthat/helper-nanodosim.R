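# shared helpers: tiny spectra built in code

# an alpha spectrum with given per-bin fluences on the standard 0-15 grid
alpha_spec <- function(fluence) {
  edges <- seq(0, 15, by = 1)
  energy_spectrum(edges, fluence, particle = "alpha")
}

# a reproducible random alpha spectrum
random_alpha_spec <- function(seed) {
  set.seed(seed)
  alpha_spec(runif(15, 0, 2))
}

# textbook lab-frame two-body energy for A(a,b)B at cos(theta_lab),
# independent of the package's CM construction
lab_two_body_energy <- function(e_a, cos_lab, m_a, m_b, m_B, q) {
  r <- sqrt(m_a * m_b * e_a) * cos_lab / (m_B + m_b)
  s <- (m_B * q + (m_B - m_a) * e_a) / (m_B + m_b)
  (r + sqrt(r^2 + s))^2
}
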