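# Shared in-code fixtures: a tiny Eurostat-dialect extract and a hand-sized
# panel with known arithmetic.

fixture_tsv <- function() {
  paste(
    "unit,icd10,geo\\time\t2017\t2012",
    "NR,TOTAL,ITC4\t318\t342",
    "NR,TOTAL,ES11\t:\t120",
    "NR,CH01,ITC4\t580 e\t600",
    sep = "\n"
  )
}

# two regions x one year, two specialties, all numbers chosen by hand
tiny_cells <- function() {
  beds <- tibble::tibble(
    dataset_code = "B", unit = "NR",
    geo = c("AA01", "AA02"), year = 2017L,
    value = c(100, 200), flags = ""
  )
  sp <- tidyr::expand_grid(geo = c("AA01", "AA02"),
                           icd10 = c("TOTAL", "CH01", "CH02"))
  disch <- tibble::tibble(
    dataset_code = "D", unit = "NR", geo = sp$geo, icd10 = sp$icd10,
    year = 2017L,
    value = c(400, 100, 300, 1000, 500, 500), flags = ""
  )
  avlos <- tibble::tibble(
    dataset_code = "A", unit = "DAY", geo = sp$geo, icd10 = sp$icd10,
    year = 2017L,
    value = c(8, 2, 10, 6, 4, 8), flags = ""
  )
  pop <- tibble::tibble(geo = c("AA01", "AA02"), year = 2017L,
                        population = c(1e6, 2e6))
  list(beds = beds, discharges = disch, avlos = avlos, population = pop)
}

tiny_panel <- function() {
  f <- tiny_cells()
  assemble_panel(f$beds, f$discharges, f$avlos, f$population)
}

# random valid activity inputs for property suites
random_activity <- function(n) {
  beds <- runif(n, 20, 2000)
  bor <- runif(n, 0.05, 0.98)
  avlos <- runif(n, 1, 20)
  occupied <- bor * beds * 365
  tibble::tibble(beds = beds,
                 discharges = occupied / avlos,
                 occupied_days = occupied)
}
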