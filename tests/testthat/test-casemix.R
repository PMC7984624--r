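# two-specialty worked benchmark used throughout: A (AvLOS 4), B (AvLOS 10),
# equal shares, overall reference AvLOS 7
worked_benchmark <- function() {
  build_benchmark(tibble::tibble(specialty = c("A", "B"),
                                 discharges = c(500, 500),
                                 avlos = c(4, 10)))
}

test_that("benchmark pooling takes sums, weighted means and shares", {
  b <- build_benchmark(tibble::tibble(
    specialty = c("A", "A", "B"),
    discharges = c(100, 300, 800),
    avlos = c(4, 8, 10)
  ))
  tb <- tidy(b)
  expect_equal(tb$ref_avlos[tb$specialty == "A"], 7)   # (100*4+300*8)/400
  expect_equal(tb$ref_share, c(1 / 3, 2 / 3))
  expect_equal(sum(tb$ref_share), 1)
  g <- glance(b)
  expect_equal(g$total_ref_discharges, 1200)
  expect_equal(g$overall_ref_avlos, sum(tb$ref_share * tb$ref_avlos))

  # a single record pools to its own profile
  one <- tibble::tibble(specialty = c("A", "B"), discharges = c(200, 800),
                        avlos = c(3, 6))
  b1 <- tidy(build_benchmark(one))
  expect_equal(b1$ref_avlos, one$avlos)
  expect_equal(b1$ref_share, c(0.2, 0.8))

  expect_error(build_benchmark(dplyr::mutate(one, discharges = 0)), "zero total")
})

test_that("worked CMI and PI values match hand summation", {
  b <- worked_benchmark()
  expect_equal(overall_ref_avlos(b), 7)
  s <- tibble::tibble(specialty = c("A", "B"), discharges = c(200, 800),
                      avlos = c(5, 12))
  expect_equal(compute_cmi(s, b), 8.8 / 7)
  expect_equal(compute_pi(s, b), 8.5 / 7)
  # restriction to a single shared specialty renormalises the shares
  expect_equal(compute_cmi(s[1, ], b), 4 / 7)
  expect_error(
    compute_cmi(tibble::tibble(specialty = "Z", discharges = 1), b),
    "shared"
  )
})

test_that("benchmark-matching mixes and stays are neutral to 1e-9", {
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- build_benchmark(tibble::tibble(
      specialty = sprintf("S%02d", 1:k),
      discharges = runif(k, 10, 1000),
      avlos = runif(k, 2, 15)
    ))
    tb <- tidy(b)
    mix <- tibble::tibble(specialty = tb$specialty,
                          discharges = tb$ref_share * 5000,
                          avlos = runif(k, 2, 15))
    expect_equal(compute_cmi(mix, b), 1, tolerance = 1e-9)
    stays <- tibble::tibble(specialty = tb$specialty,
                            discharges = runif(k, 10, 100),
                            avlos = tb$ref_avlos)
    expect_equal(compute_pi(stays, b), 1, tolerance = 1e-9)
  }
})

test_that("PI scales linearly in stays, CMI ignores them, order is irrelevant", {
  b <- worked_benchmark()
  s <- tibble::tibble(specialty = c("A", "B"), discharges = c(300, 700),
                      avlos = c(6, 9))
  k <- 1.7
  s_scaled <- dplyr::mutate(s, avlos = avlos * k)
  expect_equal(compute_pi(s_scaled, b), k * compute_pi(s, b))
  expect_equal(compute_cmi(s_scaled, b), compute_cmi(s, b))
  expect_equal(compute_pi(dplyr::mutate(s, avlos = avlos / 2), b),
               compute_pi(s, b) / 2)
  s_rev <- s[2:1, ]
  expect_equal(compute_cmi(s_rev, b), compute_cmi(s, b))
  expect_equal(compute_pi(s_rev, b), compute_pi(s, b))
})

test_that("shifting discharge share toward longer-stay specialties raises CMI", {
  b <- worked_benchmark()
  shares_b <- seq(0.1, 0.9, by = 0.1)
  cmi <- vapply(shares_b, function(w) {
    compute_cmi(tibble::tibble(specialty = c("A", "B"),
                               discharges = c(1 - w, w) * 1000), b)
  }, 1)
  expect_true(all(diff(cmi) > 0))
})

test_that("implementation agrees with an independent term-by-term oracle", {
  # oracle: literal loop over the index formulas, no shared code path
  oracle <- function(str_d, str_a, ref_d, ref_a) {
    overall <- sum((ref_d / sum(ref_d)) * ref_a)
    cmi <- 0
    for (j in seq_along(ref_a)) cmi <- cmi + ref_a[j] * str_d[j] / sum(str_d)
    pi <- 0
    for (j in seq_along(ref_a)) pi <- pi + str_a[j] * ref_d[j] / sum(ref_d)
    c(cmi = cmi / overall, pi = pi / overall)
  }
  set.seed(31)
  for (i in 1:500) {
    k <- sample(2:6, 1)
    ref_d <- runif(k, 10, 2000); ref_a <- runif(k, 1, 20)
    str_d <- runif(k, 10, 2000); str_a <- runif(k, 1, 20)
    codes <- sprintf("S%02d", 1:k)
    b <- build_benchmark(tibble::tibble(specialty = codes, discharges = ref_d,
                                        avlos = ref_a))
    s <- tibble::tibble(specialty = codes, discharges = str_d, avlos = str_a)
    exp <- oracle(str_d, str_a, ref_d, ref_a)
    expect_equal(compute_cmi(s, b), unname(exp["cmi"]), tolerance = 1e-12)
    expect_equal(compute_pi(s, b), unname(exp["pi"]), tolerance = 1e-12)
  }
})

test_that("quadrants split strictly at 1 on both axes", {
  q <- classify_quadrant(c(8.8 / 7, 1, 1.5, 0.9, 1.2),
                         c(8.5 / 7, 1, 0.8, 0.9, 1.0))
  expect_equal(as.character(q), c("ORANGE", "RED", "GREEN", "YELLOW", "ORANGE"))
  expect_equal(pi_cmi_ratio(1, 1), 1)
  expect_equal(pi_cmi_ratio(8.8 / 7, 8.5 / 7), 8.5 / 8.8)
  expect_equal(pi_cmi_ratio(2, 0.5), 0.25)
  expect_error(pi_cmi_ratio(0, 1), "non-zero")
})

test_that("per-region indices pool the benchmark per year and report coverage", {
  p <- tiny_panel()
  cm <- casemix_indices(p$specialties,
                        total_discharges = dplyr::select(
                          p$regions, geo, year, total_discharges))
  expect_equal(nrow(cm), 2)
  expect_equal(cm$coverage, c(1, 1))
  expect_equal(cm$pi_cmi_ratio, cm$pi / cm$cmi)
  # with a fixed external benchmark the same numbers come out region by region
  b <- build_benchmark(p$specialties)
  for (g in cm$geo) {
    s <- p$specialties[p$specialties$geo == g, ]
    expect_equal(cm$cmi[cm$geo == g], compute_cmi(s, b))
    expect_equal(cm$pi[cm$geo == g], compute_pi(s, b))
  }
  # a missing chapter lowers coverage below 1
  p2 <- p
  p2$specialties <- p2$specialties[-1, ]
  cm2 <- casemix_indices(p2$specialties,
                         total_discharges = dplyr::select(
                           p2$regions, geo, year, total_discharges))
  expect_lt(cm2$coverage[cm2$geo == "AA01"], 1)
})

test_that("the quadrant diagram renders with the (1,1) crosshair", {
  p <- plot_quadrants(tibble::tibble(cmi = c(8.8 / 7, 0.9), pi = c(8.5 / 7, 0.8)))
  expect_s3_class(p, "ggplot")
  expect_warning(expect_null(plot_quadrants(tibble::tibble(cmi = 1, pi = 1)[0, ])),
                 "no regions")
})
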