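test_that("lumen recovery is the normal mass inside the window", {
  expect_equal(lumen_recovery(1.71, 0.004, bd_window(-Inf, Inf)), 1)
  expect_equal(lumen_recovery(1.71, 0.004, bd_window(1.71, Inf)), 0.5)
  # one-sigma interval: frozen standard-normal value
  expect_equal(lumen_recovery(1.71, 0.004, bd_window(1.71 - 0.004, 1.71 + 0.004)),
               0.6826895, tolerance = 1e-6)
  expect_error(lumen_recovery(1.71, 0, bd_window(1.7, 1.8)), "sigma")
})

test_that("lumen and DBL abundance terms follow their closed forms", {
  expect_equal(lumen_abundance(0.02, 0, 1), 0.02)
  expect_equal(lumen_abundance(0.5, 0.3, 0), 0)
  expect_equal(lumen_abundance(0.02, 0.001, 0.5), 0.00999)
  expect_error(lumen_abundance(0.1, 1, 0.5), "p_dbl")

  dbl <- list(rho_dbl_min = 1.70, rho_dbl_max = 1.74)
  expect_equal(dbl_abundance(0.1, 0.001, bd_window(1.70, 1.74), dbl),
               0.1 * 0.001)
  expect_equal(dbl_abundance(0.1, 0.001, bd_window(1.75, 1.78), dbl), 0)
  expect_equal(dbl_abundance(0.1, 0.001, bd_window(1.70, 1.72), dbl),
               0.1 * 0.001 / 2)
  # clipping: a window wider than the DBL range recovers at most all its mass
  expect_equal(dbl_abundance(0.1, 0.001, bd_window(1.60, 1.90), dbl),
               0.1 * 0.001)
  expect_gt(dbl_abundance(0.1, 0.001, bd_window(1.60, 1.90), dbl,
                          clip = FALSE), 0.1 * 0.001)
})

test_that("fragment BD assignment composes G+C, labeling and diffusion", {
  s <- two_ref_setup()
  fb <- fragment_bd(s$frags, s$comm, s$inc, params = default_params, seed = 1)
  expect_equal(fb$rho_t, theoretical_bd(fb$gc))
  low <- fb$reference_id == "low"
  expect_true(all(fb$atom_excess[low] == 1))   # mean 100, sd 0
  expect_true(all(fb$atom_excess[!low] == 0))
  expect_equal(fb$rho[low], fb$rho_t[low] + 0.036)
  expect_equal(fb$rho[!low], fb$rho_t[!low])
  expect_equal(fb$alpha, rep(0.5, nrow(fb)))
  expect_true(all(fb$sigma > 0))
})

test_that("window abundance conserves mass and matches the shotgun limit", {
  s <- two_ref_setup()
  fb <- fragment_bd(s$frags, s$comm, s$inc, params = default_params, seed = 1)
  # p_dbl = 0 and an all-encompassing window recover alpha exactly
  ab <- fragment_window_abundance(fb, bd_window(-Inf, Inf),
                                  default_params, p_dbl = 0)
  expect_equal(ab$alpha_f, ab$alpha)
  expect_equal(ab$alpha_f, shotgun_abundance(fb)$alpha_f)
  expect_equal(ab$alpha_DBL, rep(0, nrow(ab)))
  # alpha_f = alpha_L + alpha_DBL by construction, with DBL mass present
  ab2 <- fragment_window_abundance(fb, bd_window(1.72, 1.77),
                                   default_params, p_dbl = 0.001)
  expect_equal(ab2$alpha_f, ab2$alpha_L + ab2$alpha_DBL)
  expect_true(all(ab2$p_LR >= 0 & ab2$p_LR <= 1))
})

test_that("an unlabeled mid-G+C fragment is absent from a heavy window", {
  frag <- data.frame(reference_id = "r", scaffold_id = "c", start = 0L,
                     end = 10000L, length = 10000L, gc = 0.5,
                     alpha = 0.02, atom_excess = 0, isotope = NA_character_,
                     rho_t = 1.709, rho = 1.709,
                     sigma = diffusion_sigma(1.709, 10000, default_params))
  ab <- fragment_window_abundance(frag, bd_window(1.75, 1.78),
                                  default_params, p_dbl = 0)
  expect_lt(ab$alpha_f, 1e-12)
})

test_that("labeling shifts abundance into heavier windows monotonically", {
  gp <- default_params
  win <- bd_window(1.72, 1.77)
  base <- data.frame(reference_id = "r", scaffold_id = "c", start = 0L,
                     end = 10000L, length = 10000L, gc = 0.30, alpha = 0.05)
  excesses <- seq(0, 1, by = 0.1)
  af <- vapply(excesses, function(a) {
    rho <- labeled_bd(theoretical_bd(0.30), a, "13C")
    fr <- cbind(base, atom_excess = a, isotope = "13C", rho_t = 1.6894,
                rho = rho, sigma = diffusion_sigma(rho, 10000, gp))
    fragment_window_abundance(fr, win, gp, p_dbl = 0.001)$alpha_f
  }, 0)
  # window lies entirely above rho_t: more labeling never decreases recovery
  expect_true(all(diff(af) >= -1e-15))
  # full 13C labeling beats unlabeled in the heavy window
  expect_gt(af[length(af)], af[1])
})

test_that("unlabeled high-G+C fragments contaminate the heavy window", {
  gp <- default_params
  rho <- theoretical_bd(0.65)  # 1.7237: inside [1.72, 1.77] unlabeled
  fr <- data.frame(reference_id = "r", scaffold_id = "c", start = 0L,
                   end = 10000L, length = 10000L, gc = 0.65, alpha = 0.02,
                   atom_excess = 0, isotope = NA_character_,
                   rho_t = rho, rho = rho,
                   sigma = diffusion_sigma(rho, 10000, gp))
  ab <- fragment_window_abundance(fr, bd_window(1.72, 1.77), gp, 0.001)
  expect_gt(ab$alpha_f, 0)
})

test_that("read abundance follows the length-weighted closed form", {
  expect_equal(read_abundance(1, 3000, 150), 10)
  expect_equal(read_abundance(0, 3000, 150), 0)
  expect_equal(read_abundance(0.4, 6000, 150), 2 * read_abundance(0.4, 3000, 150))
  expect_error(read_abundance(1, 100, 150), "shorter than read")
  expect_error(read_abundance(1, 100, 0), ">= 1")
  expect_equal(shotgun_abundance(c(0.02, 0)), c(0.02, 0))
})

test_that("out-of-gradient fragments contribute zero DBL and are counted", {
  gp <- default_params
  # a density so low the fragment floats above the tube's radial extent
  fr <- data.frame(reference_id = "r", scaffold_id = "c", start = 0L,
                   end = 5000L, length = 5000L, gc = 0.1, alpha = 0.1,
                   atom_excess = 0, isotope = NA_character_,
                   rho_t = 1.55, rho = 1.55,
                   sigma = diffusion_sigma(1.55, 5000, gp))
  ab <- fragment_window_abundance(fr, bd_window(1.72, 1.77), gp, 0.001)
  expect_equal(ab$alpha_DBL, 0)
  expect_equal(attr(ab, "out_of_gradient"), 1L)
})
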