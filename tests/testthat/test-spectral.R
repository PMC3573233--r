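test_that("linearisation matches a finite-difference Jacobian", {
  ss <- linearize(std_circuit, std_theta)
  Atot <- Reduce(`+`, ss$A)
  nx <- nrow(Atot)
  x0 <- numeric(nx)
  eps <- 1e-6
  Afd <- matrix(0, nx, nx)
  for (j in seq_len(nx)) {
    xp <- x0; xp[j] <- eps
    xm <- x0; xm[j] <- -eps
    Afd[, j] <- (state_derivative(xp, 0, std_circuit, std_theta) -
                   state_derivative(xm, 0, std_circuit, std_theta)) / (2 * eps)
  }
  expect_equal(Atot, Afd, tolerance = 1e-6)
  ## eigenvalues agree too
  ev1 <- sort(Re(eigen(Atot, only.values = TRUE)$values))
  ev2 <- sort(Re(eigen(Afd, only.values = TRUE)$values))
  expect_equal(ev1, ev2, tolerance = 1e-6)
})

test_that("zero extrinsic gains make the Jacobian block-diagonal by source", {
  th <- std_theta
  th$gains[extrinsic_ids(std_circuit)] <- 0
  ss <- linearize(std_circuit, th)
  Atot <- Reduce(`+`, ss$A)
  ## cortex occupies populations 1:3 (states 1:12); crossing blocks empty
  expect_equal(max(abs(Atot[13:32, 1:12])), 0)
  expect_equal(max(abs(Atot[1:12, 13:32])), 0)
  ## subcortical masses fully uncoupled from each other
  for (i in 4:7) for (j in (i + 1):8) {
    ri <- (4 * (i - 1) + 1):(4 * i); rj <- (4 * (j - 1) + 1):(4 * j)
    expect_equal(max(abs(Atot[ri, rj])), 0)
    expect_equal(max(abs(Atot[rj, ri])), 0)
  }
})

test_that("uncoupled single-mass transfer equals the alpha-kernel closed form", {
  circ <- remove_source(std_circuit, "ctx")
  for (s in c("str", "gpe", "gpi", "thal")) circ <- remove_source(circ, s)
  circ$innovation_weights["stn"] <- 1      # unit-weight innovation input
  th <- default_theta(circ)
  ss <- linearize(circ, th)
  ke <- th$syn[["kappa_e"]]; He <- th$syn[["He"]]
  for (f in c(5, 20, 40)) {
    iw <- 2i * pi * f
    Tm <- transfer_matrix(ss, 2 * pi * f)
    analytic <- ke * He / (iw + ke)^2      # input scale x alpha kernel
    expect_equal(unname(drop(Tm[1, 1])), analytic, tolerance = 1e-10)
  }
})

test_that("compiled transfer stack agrees with the plain-R transfer matrix", {
  ss <- linearize(std_circuit, off_theta())
  freqs <- c(13, 21.5, 35)
  stack <- bgdcm:::transfer_stack(ss, ss$C, freqs)
  for (i in seq_along(freqs)) {
    expect_equal(matrix(stack[, , i], nrow(ss$C)),
                 unname(transfer_matrix(ss, 2 * pi * freqs[i])),
                 tolerance = 1e-10)
  }
})

test_that("transfer magnitude rolls off at high frequency", {
  ss <- linearize(std_circuit, std_theta)
  n1 <- max(abs(transfer_matrix(ss, 2 * pi * 30)))
  n2 <- max(abs(transfer_matrix(ss, 2 * pi * 300)))
  n3 <- max(abs(transfer_matrix(ss, 2 * pi * 3000)))
  expect_gt(n1, n2)
  expect_gt(n2, n3)
  expect_lt(n3, 1e-3 * n1)
})

test_that("predicted cross-spectra are Hermitian positive semidefinite", {
  ## property over random admissible parameter draws
  set.seed(101)
  for (k in 1:5) {
    th <- std_theta
    th$gains <- th$gains * exp(rnorm(length(th$gains), 0, 0.1))
    csd <- tryCatch(predict_csd(std_circuit, th, 13:35, "on"),
                    error = function(e) NULL)
    if (is.null(csd)) next
    expect_hermitian_psd(csd)
  }
})

test_that("channel-noise-only model gives flat diagonal spectra", {
  th <- std_theta
  th$obs[] <- 0
  th$noise[["c_pink"]] <- 0
  th$noise[["c_white"]] <- 0.37
  csd <- predict_csd(std_circuit, th, 13:35, "on")
  for (i in seq_along(csd$freqs)) {
    expect_equal(unname(Re(diag(csd$S[i, , ]))), rep(0.37, 3),
                 tolerance = 1e-12)
    offd <- csd$S[i, , ][upper.tri(diag(3))]
    expect_equal(max(abs(offd)), 0)
  }
})

test_that("zero extrinsic delays equal the dense single-block linearisation", {
  circ <- build_standard_circuit(delays = c(extrinsic = 0, intrinsic = 0))
  th <- default_theta(circ)
  ss <- linearize(circ, th)
  expect_equal(length(ss$A), 1L)
  csd1 <- predict_csd(circ, th, 13:35, "on")
  ## same system expressed with artificial duplicate delay blocks of 0
  circ2 <- circ
  circ2$connections$delay <- 0
  csd2 <- predict_csd(circ2, th, 13:35, "on")
  expect_equal(csd1$S, csd2$S, tolerance = 1e-12)
})

test_that("permuting subcortical source order leaves channel spectra invariant", {
  circ2 <- build_standard_circuit()
  perm <- c(1, 2, 3, 8, 7, 6, 5, 4)       # reverse the five masses
  circ2$pops <- circ2$pops[perm, ]
  rownames(circ2$pops) <- NULL
  th <- default_theta(circ2)
  csd1 <- predict_csd(std_circuit, std_theta, 13:35, "on")
  csd2 <- predict_csd(circ2, th, 13:35, "on")
  expect_equal(csd2$S, csd1$S, tolerance = 1e-10)
})

test_that("predicted CSD matches the averaged periodogram of a long simulation", {
  ## independent oracle: Euler-Maruyama integration of the delay stochastic
  ## system, Welch-averaged, against the analytic spectral prediction
  th <- off_theta()
  dur <- 60
  X <- simulate_states(std_circuit, th, duration = dur, fs = 1000,
                       dt = 2.5e-4, seed = 99)
  idx <- bgdcm:::state_index(std_circuit)
  pop <- match("stn", std_circuit$pops$id)
  v_stn <- X[idx$ve[pop], ] - X[idx$vi[pop], ]
  w <- welch_csd(matrix(v_stn, 1), 1000, 13:35, nseg = 18)
  sp <- source_spectra(std_circuit, th, 13:35, "on")
  pred <- sp[, "stn"] * 1000               # per-sample convention
  est <- Re(w$S[, 1, 1])
  expect_lt(median(abs(est / pred - 1)), 0.25)
})

test_that("CSD containers round trip and export to CSV", {
  csd <- predict_csd(std_circuit, std_theta, 13:35, "on")
  path <- withr::local_tempfile(fileext = ".json")
  write_csd(csd, path)
  csd2 <- read_csd(path)
  expect_equal(csd2$S, csd$S)
  expect_equal(csd2$freqs, csd$freqs)
  expect_equal(csd2$labels, csd$labels)

  csvp <- withr::local_tempfile(fileext = ".csv")
  csd_to_csv(csd, csvp)
  tab <- read.csv(csvp)
  expect_equal(nrow(tab), length(csd$freqs) * 9)
  row <- tab[tab$f == 20 & tab$chan_i == "ctx" & tab$chan_j == "stn", ]
  expect_equal(row$re + 1i * row$im, csd$S[8, 1, 2])
})
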