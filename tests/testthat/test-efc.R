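test_that("an exact ellipse is a pure first harmonic", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  ell <- cbind(3 + 10 * cos(th), -2 + 5 * sin(th))
  ef <- elliptical_fourier(closed_contour(ell))
  expect_equal(unname(ef$harmonic_semiaxes[1, ]), c(10, 5), tolerance = 1e-9)
  expect_lt(max(ef$harmonic_semiaxes[-1, ]), 1e-6)
  expect_identical(efc_ratio(ef), 1e3)  # capped: no higher-harmonic content
})

test_that("semiaxes agree with a dense-quadrature oracle on a lobed shape", {
  n <- 1024
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  shape <- function(t) {
    r <- 10 * (1 + 0.2 * cos(5 * t))
    cbind(r * cos(t), r * sin(t))
  }
  ef <- elliptical_fourier(closed_contour(shape(th)))
  oracle <- efc_quadrature_oracle(shape)
  # dominant content at the expected orders (4 and 6 from r = R(1+e cos 5t))
  big <- which(oracle[, "major"] > 0.1)
  expect_setequal(big, c(1, 4, 6))
  rel <- abs(ef$harmonic_semiaxes[big, ] - oracle[big, ]) / oracle[big, ]
  expect_lt(max(rel), 0.005)
})

test_that("efc ratio is invariant to similarity transforms and traversal direction", {
  base <- lobed_contour(R = 10, eps = 0.1, order = 5)
  r0 <- efc_ratio(elliptical_fourier(closed_contour(base)))
  ang <- 0.77
  rot <- base %*% matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  variants <- list(
    scaled = base * 3,
    rotated = rot,
    translated = sweep(base, 2, c(120, -40), "+"),
    reversed = base[rev(seq_len(nrow(base))), ]
  )
  for (v in variants) {
    expect_equal(efc_ratio(elliptical_fourier(closed_contour(v))), r0,
                 tolerance = 1e-9)
  }
})

test_that("efc ratio decreases strictly along a wrinkle-amplitude family", {
  ratios <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.3), function(eps) {
    efc_ratio(elliptical_fourier(closed_contour(lobed_contour(eps = eps))))
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("reconstruction from 15 harmonics recovers band-limited contours", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 10 * (1 + 0.15 * cos(5 * th) + 0.08 * sin(3 * th) + 0.05 * cos(9 * th))
  cc <- cbind(r * cos(th), r * sin(th))
  ef <- elliptical_fourier(closed_contour(cc))
  rec <- efc_reconstruct(ef, n_points = 256)
  mean_err <- mean(sqrt(rowSums((rec - cc)^2)))
  expect_lt(mean_err / mean(sqrt(rowSums(cc^2))), 0.02)
})

test_that("degenerate contours are rejected", {
  line <- cbind(seq(0, 1, length.out = 32), seq(0, 2, length.out = 32))
  expect_error(elliptical_fourier(closed_contour(line)), "collinear")
  expect_error(closed_contour(cbind(1:5, 1:5)), "16 points")
})
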