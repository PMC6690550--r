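test_that("profile validation enforces the documented invariants", {
  expect_error(test_profile(weight = 0.5), "sum to 1")
  expect_error(test_profile(mean = -5), "positive")
  expect_error(porosity_profile("x", "diffuse",
                                data.frame(mean = 50, sd = 5, weight = 1),
                                pores_per_mm2 = 10, wall_gray = 200,
                                lumen_gray = 150),
               "bright phase")
  expect_error(porosity_profile("x", "ring",
                                data.frame(mean = 50, sd = 5, weight = 1),
                                pores_per_mm2 = 10),
               "ring_period")
  expect_error(generate_micrograph(test_profile(), side_px = 32), ">= 64")
  expect_error(generate_micrograph(test_profile(), side_px = 100, scale = -1),
               "positive")
})

test_that("a structureless profile yields a constant image and empty truth", {
  pr <- test_profile(pores_per_mm2 = 0, ray_lines_per_mm = 0, noise_sd = 0,
                     wall_gray = 117)
  img <- generate_micrograph(pr, side_px = 80, scale = 1, seed = 3)
  expect_true(all(img$pixels == 117))
  expect_identical(sum(img$truth_mask), 0L)
  expect_length(img$truth_areas, 0)
})

test_that("generation is byte-identical for a fixed seed", {
  for (pr in list(default_profiles()[["ring_a"]],
                  default_profiles()[["radial_c"]],
                  default_profiles()[["diffuse_e"]])) {
    a <- generate_micrograph(pr, side_px = 128, scale = 4.44, seed = 11)
    b <- generate_micrograph(pr, side_px = 128, scale = 4.44, seed = 11)
    expect_identical(a$pixels, b$pixels)
    expect_identical(a$truth_mask, b$truth_mask)
  }
})

test_that("truth mask agrees with a flood-fill oracle across profiles", {
  for (nm in c("diffuse_a", "ring_c", "radial_e", "ilex_like")) {
    img <- generate_micrograph(default_profiles()[[nm]], side_px = 150,
                               scale = 4.44, seed = 5)
    oracle <- flood_fill_oracle(img$truth_mask > 0, 4)
    # non-overlapping rendering: components = rendered pores
    expect_identical(oracle$n, length(img$truth_areas))
    expect_equal(sort(oracle$areas * img$scale^2), sort(img$truth_areas))
  }
})

test_that("sparse placement renders the requested number of pores", {
  # 25 small, well-spaced pores: every placement succeeds, so the flood-fill
  # component count equals the target density * area exactly
  pr <- test_profile(mean = 30, sd = 1, pores_per_mm2 = 25)
  img <- generate_micrograph(pr, side_px = 500, scale = 2, seed = 9)
  # 500 px * 2 um = 1 mm side -> 1 mm^2 -> 25 pores
  expect_length(img$truth_areas, 25L)
  oracle <- flood_fill_oracle(img$truth_mask > 0, 4)
  expect_identical(oracle$n, 25L)
  expect_equal(sort(oracle$areas), sort(as.integer(round(img$truth_areas / 4))))
})

test_that("pore diameters follow the requested mixture (KS convergence)", {
  # low density + no crowding, so rejection sampling rarely skips
  pr <- porosity_profile("ks", "diffuse",
                         data.frame(mean = c(40, 90), sd = c(5, 8),
                                    weight = c(0.5, 0.5)),
                         pores_per_mm2 = 25, noise_sd = 0,
                         ray_lines_per_mm = 0)
  imgs <- lapply(1:20, function(s)
    generate_micrograph(pr, side_px = 400, scale = 2.5, seed = s))
  areas <- unlist(lapply(imgs, `[[`, "truth_areas"))
  diam <- 2 * sqrt(areas / pi)     # equivalent-circle diameter
  expect_gte(length(diam), 450)
  mix_cdf <- function(q) 0.5 * pnorm(q, 40, 5) + 0.5 * pnorm(q, 90, 8)
  ks <- suppressWarnings(stats::ks.test(diam, mix_cdf)$statistic)
  expect_lt(ks, 0.1)
})

test_that("ring-porous images have a periodic earlywood band", {
  pr <- porosity_profile("ring_t", "ring",
                         data.frame(mean = c(200, 20), sd = c(10, 3),
                                    weight = c(0.3, 0.7)),
                         ring_period = 400, earlywood_fraction = 0.25,
                         pores_per_mm2 = 60, noise_sd = 0,
                         ray_lines_per_mm = 0)
  img <- generate_micrograph(pr, side_px = 512, scale = 2, seed = 21)
  period_px <- 400 / 2
  band_px <- 0.25 * period_px
  # earlywood vessel centroid rows, folded by the ring period, must fall in
  # one band of width earlywood_fraction * period (+ rasterisation slack)
  big_ids <- which(img$truth_areas > 5000)   # um^2; earlywood vessels
  expect_gt(length(big_ids), 3)
  big <- matrix(img$truth_mask %in% big_ids, nrow(img$truth_mask))
  idx <- which(big, arr.ind = TRUE)
  ids <- img$truth_mask[big]
  # image-border clipping shifts centroids; keep fully interior vessels
  interior <- names(which(tapply(idx[, "row"], ids, min) > 1 &
                            tapply(idx[, "row"], ids, max) < nrow(big)))
  keep <- ids %in% as.integer(interior)
  ys <- tapply(idx[keep, "row"], ids[keep], mean)
  folded <- sort(ys %% period_px)
  gaps <- diff(c(folded, folded[1] + period_px))
  window <- period_px - max(gaps)    # smallest circular window holding all
  expect_lte(window, band_px + 4)
})

test_that("radial-porous pore centres share column coordinates", {
  pr <- porosity_profile("rad_t", "radial",
                         data.frame(mean = 25, sd = 2, weight = 1),
                         pores_per_mm2 = 60, noise_sd = 0,
                         ray_lines_per_mm = 0)
  img <- generate_micrograph(pr, side_px = 300, scale = 2, seed = 13)
  # centroid column of each pore
  idx <- which(img$truth_mask > 0, arr.ind = TRUE)
  cols <- tapply(idx[, "col"], img$truth_mask[img$truth_mask > 0], mean)
  # centroids cluster on few distinct file columns
  n_files <- length(unique(round(cols / 3)))
  expect_lt(n_files, length(cols) / 2)
})

test_that("generate_dataset counts, labels and determinism", {
  prs <- list(test_profile("a"), test_profile("b", mean = 90))
  d <- generate_dataset(prs, images_per_class = 3, side_px = 64, scale = 4,
                        seed = 2)
  expect_length(d, 6L)
  labs <- vapply(d, `[[`, "", "label")
  expect_equal(unname(table(labs)[c("a", "b")]), c(3L, 3L),
               ignore_attr = TRUE)
  d2 <- generate_dataset(prs, images_per_class = 3, side_px = 64, scale = 4,
                         seed = 2)
  expect_identical(lapply(d, `[[`, "pixels"), lapply(d2, `[[`, "pixels"))
  expect_error(generate_dataset(list(test_profile("a"), test_profile("a")),
                                2, 64, 4, 1), "distinct")
  expect_error(generate_dataset(prs[1], 2, 64, 4, 1), "two profiles")
})

test_that("the default flora has 18 distinct classes spanning 3 arrangements", {
  prs <- default_profiles()
  expect_length(prs, 18L)
  expect_identical(anyDuplicated(names(prs)), 0L)
  arr <- vapply(prs, `[[`, "", "arrangement")
  expect_setequal(unique(arr), c("ring", "diffuse", "radial"))
  # the designed confound pair shares its small-pore mixture
  cer <- prs[["cerris_like"]]; ilex <- prs[["ilex_like"]]
  lw <- cer$pore_mixture[cer$pore_mixture[, "mean"] <
                           cer$earlywood_min_diameter, , drop = FALSE]
  expect_equal(unname(lw[, c("mean", "sd")]),
               unname(ilex$pore_mixture[, c("mean", "sd")]))
})
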