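## Shared fixtures: small, fast parameter sets and recordings built in code.

std_circuit <- build_standard_circuit()
std_theta <- default_theta(std_circuit)
std_priors <- default_priors(std_circuit)

## an OFF-configured theta with the generator's default strengthened set
off_theta <- function(ratios = c(ctx_stn = 1.5, gpe_stn = 1.5, stn_gpi = 1.5)) {
  th <- default_theta(std_circuit)
  th$mods[names(ratios)] <- ratios
  condition_theta(th, "off")
}

## a short recording, cached per (condition, seed) within a test run
short_recording <- local({
  cache <- list()
  function(condition = "off", seed = 421, duration = 30) {
    key <- paste(condition, seed, duration)
    if (is.null(cache[[key]])) {
      th <- if (condition == "off") off_theta() else
        condition_theta(default_theta(std_circuit), "on")
      cache[[key]] <<- simulate_recording(std_circuit, th, duration = duration,
                                          seed = seed, condition = condition)
    }
    cache[[key]]
  }
})

expect_hermitian_psd <- function(csd, tol = 1e-8) {
  ok <- vapply(seq_along(csd$freqs), function(i) {
    M <- csd$S[i, , ]
    herm_ok <- max(abs(M - Conj(t(M)))) <= tol * max(1, max(abs(M)))
    ev <- eigen((M + Conj(t(M))) / 2, symmetric = TRUE, only.values = TRUE)$values
    herm_ok && min(ev) > -tol * max(1, max(abs(ev)))
  }, TRUE)
  expect_true(all(ok))
}
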