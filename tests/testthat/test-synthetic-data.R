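test_that("rendered DAPI disks form exactly the planted components at zero noise", {
  centers <- cbind(c(20, 20, 44, 44, 32), c(20, 44, 20, 44, 32))
  tr <- image_truth(centers, radii = 5, image_shape = c(64, 64),
                    background = "none", noise_sd = 0)
  img <- generate_image_set(tr, seed = 1)$channels$DAPI
  lab <- label_components(img > 0.5, 8)
  expect_equal(max(lab), 5)
})

test_that("constructed double-positive ground truth is recorded exactly", {
  centers <- cbind(c(20, 20, 44, 44, 32), c(20, 44, 20, 44, 32))
  ml <- rbind(data.frame(cell = 1:4, channel = "GFP", level = 0.8),
              data.frame(cell = c(1, 2, 3, 5), channel = "TxRed", level = 0.9))
  tr <- image_truth(centers, radii = 5, image_shape = c(64, 64),
                    marker_levels = ml, background = "none", noise_sd = 0)
  set <- generate_image_set(tr, seed = 1)
  expect_equal(set$n_double_positive, 3L)
  expect_equal(sum(set$cells$GFP_positive), 4)
  expect_equal(sum(set$cells$TxRed_positive), 4)
})

test_that("image generation is bit-identical under a fixed seed", {
  tr <- random_image_truth(12, image_shape = c(128, 128),
                           radius_range = c(8, 10),
                           markers = list(GFP = 0.5), seed = 3)
  a <- generate_image_set(tr, seed = 9)
  b <- generate_image_set(tr, seed = 9)
  expect_identical(a$channels, b$channels)
  expect_identical(a$cells, b$cells)
  c2 <- generate_image_set(tr, seed = 10)
  expect_false(identical(a$channels$DAPI, c2$channels$DAPI))
})

test_that("scene constructor enforces its invariants", {
  expect_error(image_truth(cbind(3, 3), radii = 5, image_shape = c(64, 64)),
               "inside the image")
  expect_error(image_truth(cbind(30, 30), radii = 0.5, image_shape = c(64, 64)),
               ">= 1 pixel")
  ml <- data.frame(cell = 7, channel = "GFP", level = 1)
  expect_error(image_truth(cbind(30, 30), radii = 5, image_shape = c(64, 64),
                           marker_levels = ml), "non-existent")
  expect_error(random_image_truth(100, image_shape = c(128, 128),
                                  radius_range = c(20, 23)), "cannot pack")
})

test_that("scene TIFF round trip preserves channel structure", {
  tr <- random_image_truth(8, image_shape = c(96, 96), radius_range = c(6, 8),
                           markers = list(GFP = 0.6), seed = 5)
  set <- generate_image_set(tr, seed = 5)
  base <- file.path(withr::local_tempdir(), "scene")
  write_image_set(set, base)
  chans <- read_image_channels(paste0(base, ".tif"), c("DAPI", "GFP"))
  expect_named(chans, c("DAPI", "GFP"))
  expect_equal(dim(chans$DAPI), c(96, 96))
  side <- jsonlite::read_json(paste0(base, "_truth.json"))
  expect_equal(side$n_cells, 8)
  # stored 16-bit values reproduce the scene up to quantization
  scale <- side$intensity_scale
  expect_lt(max(abs(chans$DAPI * scale - set$channels$DAPI)), scale / 65535)
})

test_that("waveform generator records analytic energies that match quadrature", {
  wt <- waveform_truth("damped_sine", displacement_fraction = 0.3)
  f <- function(t) (wt$v_amp * exp(-t / wt$tau) * sin(2 * pi * wt$freq * t)) *
    (wt$i_amp * exp(-t / wt$tau) * sin(2 * pi * wt$freq * t - wt$phase_lag))
  num <- integrate(f, 0, wt$n_samples * wt$delta_t, rel.tol = 1e-10)$value
  expect_equal(wt$true_energy_J, num, tolerance = 1e-8)
  expect_equal(wt$displacement_energy_J / wt$discharge_energy_J, 0.3,
               tolerance = 1e-12)
})

test_that("zero-current and square-pulse waveforms have closed-form energies", {
  wt0 <- waveform_truth("damped_sine", i_amp = 0, displacement_fraction = 0.3)
  tr0 <- generate_waveform(wt0, seed = 1)
  expect_equal(energy_per_pulse(tr0$discharge), 0)
  expect_equal(energy_per_pulse(tr0$displacement), 0)

  wt <- waveform_truth("square", v_amp = 1000, i_amp = 1, square_on = 0,
                       square_width = 10 * 5e-8, displacement_fraction = 0)
  expect_equal(wt$true_energy_J, 5e-4)
  expect_equal(energy_per_pulse(generate_waveform(wt, 1)$discharge), 5e-4)
})

test_that("discharge energy exceeds displacement energy by construction", {
  wt <- waveform_truth(displacement_fraction = 0.3)
  tr <- generate_waveform(wt, seed = 2)
  expect_gt(energy_per_pulse(tr$discharge), energy_per_pulse(tr$displacement))
  expect_identical(generate_waveform(wt, 2)$discharge$current,
                   tr$discharge$current)
  expect_error(waveform_truth(v_amp = Inf), "non-finite")
})

test_that("planted DE genes shift by the requested effect size", {
  tr <- de_truth(n_genes = 1000, planted_sets = c(UP = 50), effect_size = 2)
  de <- generate_de_table(tr, seed = 11)
  planted <- de$gene %in% tr$planted_sets$UP
  # sample-mean oracle: 50 draws at sd 0.5 -> SE ~ 0.07
  expect_equal(mean(de$log2fc[planted]), 2, tolerance = 0.25)
  expect_lt(abs(mean(de$log2fc[!planted])), 0.1)
  expect_lt(median(de$pvalue[planted]), 0.1)
  expect_identical(de, generate_de_table(tr, seed = 11))
})

test_that("pi scores are sign-balanced when nothing is planted", {
  signs <- vapply(1:10, function(s) {
    de <- generate_de_table(de_truth(n_genes = 400,
                                     planted_sets = integer(0)), seed = s)
    mean(sign(pi_score(de$log2fc, de$pvalue)))
  }, numeric(1))
  expect_lt(abs(mean(signs)), 0.05)
})

test_that("DE generator validates and warns on degenerate requests", {
  expect_error(de_truth(n_genes = 30, planted_sets = c(A = 40)),
               "exceed")
  tr <- de_truth(n_genes = 100, planted_sets = c(A = 10), effect_size = 0)
  expect_warning(generate_de_table(tr, seed = 1), "effect_size is 0")
  tr2 <- de_truth(n_genes = 100, planted_sets = c(A = 10, B = 20))
  expect_length(intersect(tr2$planted_sets$A, tr2$planted_sets$B), 0)
  expect_true(all(unlist(tr2$planted_sets) %in% tr2$gene_ids))
})

test_that("DE table and GMT round trip through disk", {
  tr <- de_truth(n_genes = 50, planted_sets = c(A = 5, B = 7))
  de <- generate_de_table(tr, seed = 2)
  base <- file.path(withr::local_tempdir(), "de")
  write_de_table(de, base)
  back <- read_de_table(paste0(base, ".tsv"))
  expect_equal(back$log2fc, de$log2fc, tolerance = 1e-6)
  sets <- read_gmt(paste0(base, ".gmt"))
  expect_identical(sets, tr$planted_sets)
})
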