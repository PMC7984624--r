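test_that("regions are placed at exact diagram coordinates", {
  r <- gen_region_at(0.80, 2.0, beds = 100)
  expect_equal(r$discharges, 3650)
  expect_equal(r$avlos, 8)
  z <- classify_bj(r)
  expect_equal(as.character(z$zone), "GREEN")
  expect_equal(as.character(classify_bj(gen_region_at(0.70, 0.9, 50))$zone), "RED")

  # sampling anywhere inside the open green box stays green
  set.seed(17)
  pts <- tibble::tibble(bor = runif(100, 0.751, 0.849),
                        toi = runif(100, 1.001, 2.999))
  r <- gen_region_at(pts$bor, pts$toi, beds = 120)
  expect_true(all(classify_bj(r)$zone == "GREEN"))
})

test_that("specialty profiles hit PI exactly and CMI by bisection", {
  b <- build_benchmark(tibble::tibble(specialty = c("A", "B"),
                                      discharges = c(500, 500),
                                      avlos = c(4, 10)))
  # neutral targets return the benchmark profile itself
  p0 <- gen_specialty_profile(b, 1, 1)
  expect_equal(attr(p0, "theta"), 0)
  expect_equal(p0$share, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(p0$avlos, c(4, 10))

  # the worked mix (0.2, 0.8) is the unique tilt with CMI = 8.8/7
  p1 <- gen_specialty_profile(b, 8.8 / 7, 1)
  expect_equal(p1$share, c(0.2, 0.8), tolerance = 1e-4)

  expect_error(gen_specialty_profile(b, 2, 1), "attainable")

  # random interior targets: CMI within 1e-6 in <= 60 steps, PI exact
  set.seed(29)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    bb <- build_benchmark(tibble::tibble(
      specialty = sprintf("S%d", 1:k),
      discharges = runif(k, 50, 500),
      avlos = runif(k, 2, 14)
    ))
    lohi <- range(tidy(bb)$ref_avlos) / overall_ref_avlos(bb)
    target <- runif(1, lohi[1] + 0.05 * diff(lohi), lohi[2] - 0.05 * diff(lohi))
    pi_t <- runif(1, 0.5, 1.5)
    pr <- gen_specialty_profile(bb, target, pi_t)
    expect_lte(attr(pr, "steps"), 60)
    expect_lte(abs(attr(pr, "cmi_achieved") - target), 1e-6)
    s <- tibble::tibble(specialty = pr$specialty, discharges = pr$share,
                        avlos = pr$avlos)
    expect_lt(abs(compute_cmi(s, bb) - target), 1.1e-6)
    expect_equal(compute_pi(s, bb), pi_t, tolerance = 1e-12)
  }
})

test_that("stratified assignment matches the configured mixes exactly", {
  cfg <- synthetic_config(countries = c(AA = 20), years = 2017,
                          zone_mix = c(GREEN = 0.5, YELLOW = 0.25, RED = 0.25),
                          seed = 4)
  sp <- gen_panel(cfg)
  expect_equal(as.vector(table(sp$truth$intended_zone)[c("GREEN", "YELLOW", "RED")]),
               c(10, 5, 5))
  # indivisible mixes fall back to largest-remainder apportionment
  expect_equal(bedbench:::largest_remainder(c(0.45, 0.20, 0.35), 10), c(5, 2, 3))
  expect_equal(sum(bedbench:::largest_remainder(c(1, 1, 1) / 3, 100)), 100)
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- synthetic_config(countries = c(AA = 8, BB = 8), years = 2017, seed = 99)
  a <- gen_panel(cfg)
  b <- gen_panel(cfg)
  expect_identical(a$panel$regions, b$panel$regions)
  expect_identical(a$panel$specialties, b$panel$specialties)
  expect_identical(a$truth, b$truth)
})

test_that("noise-free panels carry their intended labels exactly", {
  sp <- gen_panel(synthetic_config(countries = c(AA = 12, BB = 12),
                                   years = c(2012, 2017), seed = 21))
  expect_true(all(sp$truth$zone == sp$truth$intended_zone))
  expect_true(all(sp$truth$quadrant == sp$truth$intended_quadrant))
  # exact coordinates: recomputed BOR/TOI equal the placed ones
  expect_equal(sp$truth$bor, sp$truth$intended_bor, tolerance = 1e-9)
  expect_equal(sp$truth$toi, sp$truth$intended_toi, tolerance = 1e-9)
})

test_that("label recovery degrades monotonically with noise", {
  agree <- vapply(c(0, 0.1, 0.4), function(ns) {
    sp <- gen_panel(synthetic_config(countries = c(AA = 15, BB = 15),
                                     years = 2017, noise_sd = ns, seed = 5))
    mean(sp$truth$zone == sp$truth$intended_zone &
           sp$truth$quadrant == sp$truth$intended_quadrant)
  }, 1)
  expect_equal(agree[1], 1)
  expect_true(all(diff(agree) < 0))
})

test_that("fixtures export and re-ingest to an equal panel", {
  sp <- gen_panel(synthetic_config(countries = c(AA = 6, BB = 6),
                                   years = c(2012, 2017), seed = 12))
  dir <- withr::local_tempdir()
  paths <- export_fixture(sp, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fixture(dir)
  ord <- function(d) dplyr::arrange(d, geo, year)
  expect_equal(ord(back$regions), ord(sp$panel$regions), tolerance = 1e-12)
  expect_equal(
    dplyr::arrange(back$specialties, geo, year, specialty),
    dplyr::arrange(sp$panel$specialties, geo, year, specialty),
    tolerance = 1e-12
  )
  expect_equal(nrow(skipped_regions(back)), 0)

  # missing-data injection writes ":" cells that parse as missing
  set.seed(8)
  dir2 <- withr::local_tempdir()
  export_fixture(sp, dir2, missing_rate = 0.3)
  expect_true(any(grepl("\t:", readLines(file.path(dir2, "avlos.tsv")))))
  back2 <- read_fixture(dir2)
  expect_lt(nrow(back2$specialties), nrow(sp$panel$specialties))
  expect_true(any(back2$regions$coverage < 1))
})
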