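test_that("Kd to free-energy conversion follows dG = RT ln(Kd) and round-trips", {
  expect_equal(deltaGFromKd(1), 0)
  # RT ln(1e-9) at 298.15 K with R = 1.987e-3, computed by hand
  expect_equal(deltaGFromKd(1e-9), 1.987e-3 * 298.15 * log(1e-9),
               tolerance = 1e-12)
  expect_equal(deltaGFromKd(1e-9), -12.277, tolerance = 1e-4)
  expect_gt(deltaGFromKd(10), 0)  # non-binder: Kd above 1 M

  for (kd in 10^seq(-15, 3, by = 1.5))
    expect_equal(kdFromDeltaG(deltaGFromKd(kd)), kd, tolerance = 1e-12)

  p <- thermoParams(temperature = 310)
  expect_equal(deltaGFromKd(1e-6, p), 1.987e-3 * 310 * log(1e-6))
  expect_error(deltaGFromKd(0), "positive")
  expect_error(deltaGFromKd(-1e-9), "positive")
  expect_error(thermoParams(temperature = -5), "temperature")
})

test_that("ligand efficiency divides free energy by heavy atoms under both conventions", {
  expect_equal(as.numeric(ligandEfficiency(-12.28, 25)), 12.28 / 25)
  expect_equal(as.numeric(ligandEfficiency(-4, 10)), 0.4)
  expect_equal(as.numeric(ligandEfficiency(-4, 10, "signed")), -0.4)
  expect_equal(as.numeric(ligandEfficiency(0, 10)), 0)
  expect_identical(attr(ligandEfficiency(-4, 10), "convention"), "magnitude")
  expect_error(ligandEfficiency(-4, 0), "nHeavy")

  # homogeneity: scaling dG scales LE; integer-scaling N divides it
  le <- as.numeric(ligandEfficiency(-6.3, 12))
  expect_equal(as.numeric(ligandEfficiency(-6.3 * 3, 12)), 3 * le)
  expect_equal(as.numeric(ligandEfficiency(-6.3, 12 * 2)), le / 2)
})

test_that("group efficiency is the per-added-atom affinity gain", {
  expect_equal(as.numeric(groupEfficiency(-5, 10, -7, 14, "signed")), -0.5)
  expect_equal(as.numeric(groupEfficiency(-5, 10, -7, 14)), 0.5)
  # atoms added with no affinity gain contribute nothing
  expect_equal(as.numeric(groupEfficiency(-5, 10, -5, 14)), 0)
  expect_error(groupEfficiency(-5, 10, -7, 10), "delta N = 0")
})

test_that("group efficiency telescopes exactly along a chain A -> B -> C", {
  set.seed(11)
  for (i in 1:50) {
    dg <- sort(-runif(3, 1, 12))  # C strongest
    n <- cumsum(sample(3:9, 3))
    geAB <- as.numeric(groupEfficiency(dg[1], n[1], dg[2], n[2], "signed"))
    geBC <- as.numeric(groupEfficiency(dg[2], n[2], dg[3], n[3], "signed"))
    geAC <- as.numeric(groupEfficiency(dg[1], n[1], dg[3], n[3], "signed"))
    expect_equal(geAC * (n[3] - n[1]),
                 geAB * (n[2] - n[1]) + geBC * (n[3] - n[2]))
  }
})

test_that("heavy atoms are counted from SMILES including implicit aromatics", {
  expect_equal(unname(heavyAtomCount("c1ccccc1")), 6L)
  expect_equal(unname(heavyAtomCount("CCO")), 3L)
  expect_equal(unname(heavyAtomCount("C1CCCCC1N")), 7L)
  expect_equal(unname(heavyAtomCount(c("CCO", "c1ccccc1"))), c(3L, 6L))
  expect_error(heavyAtomCount("notasmiles(("), "cannot parse SMILES")
})

test_that("efficiencyTable flags non-binders and records the convention", {
  lib <- PocketLibrary(data.frame(
    fragment_id = c("f1", "f2"), pocket_id = c("P1", "P2"),
    delta_g = c(-3.3, 0.5), n_heavy = c(11L, 10L)))
  tab <- efficiencyTable(lib)
  expect_equal(tab$le, c(0.3, 0.05))
  expect_equal(tab$is_binder, c(TRUE, FALSE))
  expect_equal(unique(tab$convention), "magnitude")
  tabS <- efficiencyTable(lib, "signed")
  expect_equal(tabS$le, c(-0.3, 0.05))
})
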