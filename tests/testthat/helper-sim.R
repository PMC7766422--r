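# One noise-free reference simulation shared across test files.
.sim_cache <- new.env(parent = emptyenv())

sim_clean <- function() {
  if (is.null(.sim_cache$clean)) {
    .sim_cache$clean <- simulate_circuit(seed = 42, noise_sd = 0,
                                         breath_noise = 0)
  }
  .sim_cache$clean
}

sim_noisy <- function() {
  if (is.null(.sim_cache$noisy)) {
    .sim_cache$noisy <- simulate_circuit(seed = 11)
  }
  .sim_cache$noisy
}

# Minimal kinematic series for metric tests (constant dt grid).
make_series <- function(t, v, power = NULL, a = NULL, heading = NULL) {
  df <- tibble::tibble(t = t, v_s = v)
  if (!is.null(a)) df$a <- a
  if (!is.null(power)) df$power <- power
  if (!is.null(heading)) df$heading <- heading
  structure(df, class = c("kinematic_series", class(tibble::tibble())))
}
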