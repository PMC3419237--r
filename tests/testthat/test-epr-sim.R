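test_that("resonance condition matches closed-form constant arithmetic", {
  expect_equal(resonance_field(2.0023, 9.67), oracle_resonance_mT(2.0023, 9.67),
               tolerance = 1e-12)
  expect_equal(resonance_field(2.0073, 285), oracle_resonance_mT(2.0073, 285),
               tolerance = 1e-12)
  # printed-precision sanity on the X-band free-electron-like line
  expect_equal(round(resonance_field(2.0023, 9.67), 2), 345.05)
  # B is inversely proportional to g
  expect_equal(resonance_field(1.0, 9.67), 2 * resonance_field(2.0, 9.67))
  expect_error(resonance_field(-1, 9.67), "positive")
  expect_error(resonance_field(2, 0), "positive")
  # field_to_g inverts the map
  expect_equal(field_to_g(resonance_field(2.0042, 285), 285), 2.0042)
})

test_that("effective g interpolates the tensor correctly", {
  g <- c(2.0073, 2.0042, 2.0022)
  expect_equal(effective_g(c(1, 0, 0), g), 2.0073)
  expect_equal(effective_g(c(0, 0, 1), g), 2.0022)
  iso <- c(2.005, 2.005, 2.005)
  for (d in list(c(1, 0, 0), c(0, 1, 0), sqrt(c(1, 1, 1) / 3)))
    expect_equal(effective_g(d, iso), 2.005)
  expect_equal(effective_g(c(1, 1, 0) / sqrt(2), g),
               sqrt((2.0073^2 + 2.0042^2) / 2))
  expect_equal(round(effective_g(c(1, 1, 0) / sqrt(2), g), 5), 2.00575)
  expect_error(effective_g(c(1, 1, 0), g), "unit")
})

test_that("spin-system construction enforces its invariants", {
  expect_error(spin_system("x", c(2.0022, 2.0042, 2.0073), linewidth = c(4, 4, 4)),
               "ordered")
  expect_error(spin_system("x", c(2, 2, 2), linewidth = c(0, 4, 4)), "positive")
  expect_error(spin_system("x", c(0.5, 0.4, 0.3), linewidth = c(4, 4, 4)), "1, 3")
  many <- replicate(9, list(label = "H", I = 0.5, A = c(1, 1, 1)),
                    simplify = FALSE)
  expect_error(spin_system("x", c(2, 2, 2), many, c(4, 4, 4)), "8")
  expect_error(spin_system("x", c(2, 2, 2),
                           list(list(label = "H", I = 0.3, A = c(1, 1, 1))),
                           c(4, 4, 4)), "half-integer")
})

test_that("presets carry the published g-values and hyperfine structure", {
  expect_equal(preset_spin_system("mouse_R2")$g, c(2.0076, 2.0043, 2.0022))
  expect_equal(preset_spin_system("carp_p53R2i")$g, c(2.0074, 2.0042, 2.0022))
  mv <- preset_spin_system("mv_carp_R2ii")
  expect_equal(mv$g, c(1.92, 1.73, 1.61))
  expect_length(mv$hyperfine, 0)
  ty <- preset_spin_system("carp_R2ii")
  expect_length(ty$hyperfine, 4)
  expect_equal(ty$hyperfine[[1]]$A, c(21.4, 19.0, 21.5))
  expect_equal(ty$linewidth, c(4.5, 3.5, 4.4))
  expect_error(preset_spin_system("no_such_species"), "available")
})

test_that("degenerate powder reduces to a single line at the isotropic g", {
  iso <- spin_system("iso", c(2.005, 2.005, 2.005), linewidth = c(5, 5, 5))
  sp <- powder_spectrum(iso, 9.67, n_points = 2048, orientations = 400)
  i <- which(diff(sign(sp$intensity)) < 0)[1]
  zc <- sp$field[i] - sp$intensity[i] * diff(sp$field[i + 0:1]) /
    diff(sp$intensity[i + 0:1])
  expect_lt(abs(zc - resonance_field(2.005, 9.67)), diff(sp$field[1:2]))
  # symmetric derivative line
  expect_equal(max(sp$intensity), -min(sp$intensity), tolerance = 1e-6)
})

test_that("a single-axis tensor reproduces the single-crystal resonance", {
  # powder average collapsed onto one principal value equals a single
  # crystal line at that axis' resonance field
  for (gk in c(2.0073, 2.0022)) {
    axis_sys <- spin_system("axis", rep(gk, 3), linewidth = c(4, 4, 4))
    sp <- powder_spectrum(axis_sys, 285, n_points = 1024, orientations = 400)
    i <- which(diff(sign(sp$intensity)) < 0)[1]
    zc <- sp$field[i] - sp$intensity[i] * diff(sp$field[i + 0:1]) /
      diff(sp$intensity[i + 0:1])
    expect_lt(abs(zc - resonance_field(gk, 285)), diff(sp$field[1:2]))
  }
})

test_that("an isotropic I = 1/2 coupling splits the line into a doublet of separation A", {
  dbl <- spin_system("dbl", c(2.005, 2.005, 2.005),
                     list(list(label = "H", I = 0.5, A = c(8, 8, 8))),
                     linewidth = c(1.5, 1.5, 1.5))
  sp <- powder_spectrum(dbl, 9.67, n_points = 4096, orientations = 400)
  mx <- which(diff(sign(diff(sp$intensity))) == -2) + 1L
  mx <- mx[sp$intensity[mx] > 0.1]
  expect_length(mx, 2)
  expect_lt(abs(diff(sp$field[mx]) - 0.8), 2 * diff(sp$field[1:2]))  # 8 G = 0.8 mT
})

test_that("n equivalent-weight I = 1/2 nuclei give 2^n resolved components", {
  # brute-force oracle: first-order positions are all sums of +/- a_i/2
  As <- c(24, 8)  # Gauss, well separated relative to the 0.8 G width
  sys <- spin_system("quartet", c(2.005, 2.005, 2.005),
                     list(list(label = "H1", I = 0.5, A = rep(As[1], 3)),
                          list(label = "H2", I = 0.5, A = rep(As[2], 3))),
                     linewidth = c(0.8, 0.8, 0.8))
  sp <- powder_spectrum(sys, 9.67, n_points = 8192, orientations = 400)
  mx <- which(diff(sign(diff(sp$intensity))) == -2) + 1L
  mx <- mx[sp$intensity[mx] > 0.1]
  expect_length(mx, 4)
  # component centres are all sums of +/- a_i/2; each derivative maximum
  # sits a common sigma below its centre, so compare the spacing pattern
  want <- sort(as.vector(outer(c(-1, 1) * As[1] / 20,
                               c(-1, 1) * As[2] / 20, `+`)))
  got <- sort(sp$field[mx])
  expect_equal(diff(got), diff(want), tolerance = 0.01)
  # equal component weights: derivative maxima of equal height
  expect_lt(diff(range(sp$intensity[mx])) / max(sp$intensity[mx]), 0.02)
})

test_that("orientation-grid refinement leaves extracted g-values stable", {
  g5h <- extract_g(powder_spectrum(preset_spin_system("mv_carp_R2ii"), 9.67,
                                   n_points = 2048, orientations = 500),
                   "turning_points")
  g5k <- extract_g(powder_spectrum(preset_spin_system("mv_carp_R2ii"), 9.67,
                                   n_points = 2048, orientations = 5000),
                   "turning_points")
  expect_lt(max(abs(g5h$fields_mT - g5k$fields_mT)), 0.4)  # ~ 1 grid step
})

test_that("high field resolves the g1/g2 anisotropy that X-band leaves overlapped", {
  g <- preset_spin_system("carp_R2i")$g
  # predicted feature separation B * dg / g vs the hyperfine-broadened
  # envelope width (sum of the largest couplings, in mT)
  envelope <- sum(vapply(preset_spin_system("carp_R2i")$hyperfine,
                         function(h) max(abs(h$A)), numeric(1))) * 0.1
  sep_hf <- resonance_field(g[2], 285) - resonance_field(g[1], 285)
  sep_x <- resonance_field(g[2], 9.67) - resonance_field(g[1], 9.67)
  expect_gt(sep_hf, envelope)       # resolved at 285 GHz (~15.7 mT apart)
  expect_lt(sep_x, envelope)        # buried at X-band (~0.5 mT apart)
  expect_equal(sep_hf, 15.7, tolerance = 0.01)
  # and empirically: turning points at 285 GHz recover g1 closely
  sp <- powder_spectrum(preset_spin_system("carp_R2i"), 285,
                        n_points = 2048, orientations = 500)
  tp <- extract_g(sp, "turning_points",
                  known_system = preset_spin_system("carp_R2i"))
  expect_lt(abs(tp$g[1] - g[1]), 0.001)
})

test_that("refinement of a self-simulated spectrum is a fixed point", {
  sys <- preset_spin_system("mv_carp_R2ii")
  obs <- powder_spectrum(sys, 9.67, n_points = 1024, orientations = 500)
  fit <- fit_spin_system(obs, sys, free = "g", orientations = 500)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$system$g - sys$g)), 1e-5)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("spin-system JSON round trips", {
  sys <- preset_spin_system("mouse_R2")
  f <- withr::local_tempfile(fileext = ".json")
  write_spin_system(sys, f)
  back <- read_spin_system(f)
  expect_equal(back$g, sys$g)
  expect_equal(back$linewidth, sys$linewidth)
  expect_equal(lapply(back$hyperfine, `[[`, "A"),
               lapply(sys$hyperfine, `[[`, "A"))
})
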