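test_that("reflectance respects causality, positivity and radial ordering", {
  p <- standard_props()
  t <- seq(-200, 4000, by = 100)
  R <- td_reflectance(30, t, p)
  expect_true(all(R[t <= 0] == 0))
  expect_true(all(R >= 0))
  expect_true(all(is.finite(R)))
  tp <- t[t > 0]
  expect_true(all(td_reflectance(20, tp, p) < td_reflectance(10, tp, p)))
  expect_error(td_reflectance(-5, tp, p))
  expect_error(td_reflectance(30, c(100, 100, 200), p))
})

test_that("absorption factors out as the time-domain Beer-Lambert term", {
  # arithmetic oracle: R(mua)/R(0) = exp(-mua * (c/n) * t)
  p1 <- optical_props(0.1, 10, n_medium = 1.4)
  p0 <- optical_props(0, 10, n_medium = 1.4)
  ratio <- td_reflectance(20, 1000, p1) / td_reflectance(20, 1000, p0)
  expect_equal(ratio, exp(-0.1 * 0.0299792458 / 1.4 * 1000), tolerance = 1e-12)
  expect_equal(ratio, 0.1174932, tolerance = 1e-6)

  # same identity for the slab, to machine precision
  g <- geometry("transmittance", rho_mm = 0, thickness_mm = 20)
  t <- seq(100, 4000, by = 100)
  T1 <- td_transmittance(t, optical_props(0.2, 8, 1.55), g)
  T0 <- td_transmittance(t, optical_props(0, 8, 1.55), g)
  v <- 0.0299792458 / 1.55
  expect_equal(T1 / T0, exp(-0.2 * v * t), tolerance = 1e-12)
})

test_that("slab image-source series is converged at its truncation tolerance", {
  g <- geometry("transmittance", rho_mm = 0, thickness_mm = 20)
  p <- optical_props(0.05, 15)
  t <- seq(50, 6000, by = 50)
  coarse <- td_transmittance(t, p, g, tol = 1e-9)
  fine <- td_transmittance(t, p, g, tol = 1e-15)  # high-order oracle
  expect_true(all(td_transmittance(c(-50, 0), p, g) == 0))
  rel <- abs(coarse - fine) / pmax(fine, max(fine) * 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("Born perturbation is first-order, absorbing and self-consistent", {
  p <- standard_props()
  t <- seq(25, 5000, by = 25)
  R0 <- td_reflectance(30, t, p)

  # zero perturbation is the identity
  inc0 <- inclusion_spec(15, delta_mua = 0)
  expect_equal(as.numeric(td_perturbed_reflectance(30, t, p, inc0)),
               as.numeric(R0))

  # an absorbing perturbation only removes photons
  inc <- inclusion_spec(15)
  Rp <- suppressWarnings(td_perturbed_reflectance(30, t, p, inc))
  expect_true(all(Rp <= R0 + 1e-300))
  expect_true(all(Rp >= 0))

  # doubling delta_mua x volume doubles the relative contrast exactly
  # (first-order by construction); small perturbation avoids clipping
  incA <- inclusion_spec(15, delta_mua = 0.01)
  incB <- inclusion_spec(15, delta_mua = 0.02)
  cA <- 1 - td_perturbed_reflectance(30, t, p, incA) / R0
  cB <- 1 - td_perturbed_reflectance(30, t, p, incB) / R0
  # only where the contrast is resolvable in double precision: below ~1e-6
  # the subtraction R0 + dR itself rounds away the comparison
  sig <- which(cB > 1e-6)
  expect_gt(length(sig), 100)
  expect_lt(max(abs(cB[sig] - 2 * cA[sig]) / cB[sig]), 1e-9)

  # quadrature refinement: 4x finer grid agrees within 1%
  late <- t >= 500
  Rp_fine <- suppressWarnings(
    td_perturbed_reflectance(30, t, p, inc, dt_quad_ps = 25 / 16))
  dA <- (R0 - Rp)[late]
  dB <- (R0 - Rp_fine)[late]
  expect_lt(max(abs(dA - dB) / pmax(dB, max(dB) * 1e-9)), 0.01)
})

test_that("Born-regime violation is flagged and clipped", {
  p <- standard_props()
  t <- seq(25, 3000, by = 25)
  inc <- inclusion_spec(5, delta_mua = 2, volume_cm3 = 5)
  expect_warning(Rp <- td_perturbed_reflectance(30, t, p, inc), "clipped")
  expect_true(attr(Rp, "born_clipped"))
  expect_true(all(Rp >= 0))
})

test_that("constructors enforce the physical invariants", {
  expect_error(optical_props(-0.1, 10))
  expect_error(optical_props(0.1, 0))
  expect_error(optical_props(0.1, 10, n_medium = 0.9))
  expect_error(geometry("transmittance", rho_mm = 0))
  expect_error(geometry(rho_mm = -1))
  expect_error(inclusion_spec(0))
  expect_identical(inclusion_spec(15)$delta_mua, 0.17)
  expect_identical(inclusion_spec(15)$volume_cm3, 1.0)
})
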