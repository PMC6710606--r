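test_that("pruned screen matches exhaustive enumeration on random libraries", {
  set.seed(61)
  for (i in 1:40) {
    lib <- randomLibrary()
    cutoff <- runif(1, 0.2, 0.5)
    for (mode in c("arithmetic", "wrms")) {
      res <- screenFragments(lib, screenConfig(cutoff, mode))
      oracle <- bruteForceScreen(lib, cutoff, mode)
      expect_identical(comboKeys(res), oracle$combos)
      expect_equal(sort(accepted(res)$le_t_app), oracle$leTApp)
      expect_identical(classification(res)[names(oracle$classification)],
                       oracle$classification)
    }
  }
})

test_that("rescue annotations mark exactly the below-cutoff members of accepted combos", {
  lib <- libraryFromLes(list(c(0.5, 0.3), c(0.5, 0.3)))
  res <- screenFragments(lib, screenConfig(0.4))
  acc <- accepted(res)
  expect_equal(nrow(acc), 3)
  expect_equal(acc$le_t_app, c(0.5, 0.4, 0.4))
  # the all-strong combination rescues nobody
  expect_identical(acc$rescued_fragment_ids[acc$le_t_app == 0.5], "")
  low <- acc$rescued_fragment_ids[acc$le_t_app < 0.5]
  expect_setequal(low, c("P1:f1_2", "P2:f2_2"))
  expect_equal(unname(classification(res)[c("P1:f1_2", "P2:f2_2")]),
               c("rescued", "rescued"))
})

test_that("a vacuous cutoff accepts everything and rejects nobody", {
  set.seed(62)
  lib <- randomLibrary()
  for (mode in c("arithmetic", "wrms")) {
    res <- screenFragments(lib, screenConfig(0, mode))
    expect_equal(nrow(accepted(res)), screenStats(res)$combinations_total)
    expect_false(any(classification(res) == "rejected"))
  }
})

test_that("raising the cutoff shrinks the accepted set; adding fragments grows it", {
  set.seed(63)
  lib <- randomLibrary()
  for (mode in c("arithmetic", "wrms")) {
    sets <- lapply(c(0.2, 0.3, 0.4, 0.5), function(ct)
      comboKeys(screenFragments(lib, screenConfig(ct, mode))))
    for (k in 2:length(sets))
      expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
  # augment one pocket with an extra fragment: previously accepted combos stay
  df <- fragments(lib)
  extra <- data.frame(fragment_id = "extra", pocket_id = df$pocket_id[1],
                      delta_g = -0.45 * 12, n_heavy = 12L,
                      smiles = NA_character_)
  lib2 <- PocketLibrary(rbind(df, extra))
  for (mode in c("arithmetic", "wrms")) {
    before <- comboKeys(screenFragments(lib, screenConfig(0.35, mode)))
    after <- comboKeys(screenFragments(lib2, screenConfig(0.35, mode)))
    expect_true(all(before %in% after))
  }
})

test_that("no pocket can supply a strong partner: nothing is accepted or rescued", {
  lib <- libraryFromLes(list(c(0.30, 0.22), c(0.28, 0.15), c(0.31, 0.10)))
  for (mode in c("arithmetic", "wrms")) {
    res <- screenFragments(lib, screenConfig(0.45, mode))
    expect_equal(nrow(accepted(res)), 0)
    expect_true(all(classification(res) == "rejected"))
    expect_equal(unname(classCounts(res)["rescued"]), 0L)
  }
})

test_that("non-binders are refused by default but screenable on request", {
  lib <- PocketLibrary(data.frame(
    fragment_id = c("good", "inert", "b1"), pocket_id = c("P1", "P1", "P2"),
    delta_g = c(-5, 1.2, -4.8), n_heavy = c(10L, 10L, 12L)))
  res <- screenFragments(lib, screenConfig(0.35))
  expect_identical(unname(classification(res)["P1:inert"]), "rejected")
  expect_equal(nrow(accepted(res)), 1)
  resAll <- screenFragments(lib, screenConfig(0.1, allowNonbinders = TRUE))
  expect_equal(screenStats(resAll)$combinations_total, 2)

  allInert <- PocketLibrary(data.frame(
    fragment_id = c("n1", "n2"), pocket_id = c("P1", "P2"),
    delta_g = c(0.5, 2), n_heavy = c(10L, 10L)))
  expect_error(screenFragments(allInert, screenConfig(0.3)), "non-binders")
  oneEmpty <- PocketLibrary(data.frame(
    fragment_id = c("g", "n"), pocket_id = c("P1", "P2"),
    delta_g = c(-5, 0.5), n_heavy = c(10L, 10L)))
  expect_error(screenFragments(oneEmpty, screenConfig(0.3)), "pocket")
})

test_that("the requirement on unfilled pockets follows the subtractive average", {
  lib <- libraryFromLes(list(c(0.3, 0.6), c(0.6, 0.2), c(0.6, 0.2)))
  cfg <- screenConfig(0.4)
  # nothing chosen: the requirement is the cutoff itself
  r0 <- requiredLeForRemaining(character(0), lib, cfg)
  expect_equal(r0$leDelta, 0.4)
  # one weak fragment chosen in a 3-pocket screen
  r1 <- requiredLeForRemaining(c(P1 = "f1_1"), lib, cfg)
  expect_equal(r1$leDelta, (3 * 0.4 - 0.3) / 2)
  expect_true(r1$feasible)  # both other pockets offer 0.6
  # two strong fragments already chosen fully fund the rescue
  r2 <- requiredLeForRemaining(c(P2 = "f2_1", P3 = "f3_1"), lib, cfg)
  expect_equal(r2$leDelta, 0.0)
  # an unreachable cutoff is flagged infeasible
  r3 <- requiredLeForRemaining(c(P1 = "f1_1"), lib, screenConfig(0.65))
  expect_false(r3$feasible)
  expect_error(requiredLeForRemaining(c(P9 = "f"), lib, cfg), "pocket")
})

test_that("per-pocket bounds are admissible: pruning never loses an accepted combination", {
  lib <- libraryFromLes(list(c(0.2, 0.5, 0.4), c(0.5, 0.45)))
  expect_equal(pruneBound(lib, "P1"), 0.5)
  expect_equal(pruneBound(lib, "P2"), 0.5)
  expect_error(pruneBound(lib, "nope"), "unknown")
  # a requirement above every remaining maximum leaves the branch dead:
  # the oracle confirms no accepted combination extends a 0.2 choice
  cfg <- screenConfig(0.56)
  r <- requiredLeForRemaining(c(P1 = "f1_1"), lib, cfg)
  expect_gt(r$leDelta, pruneBound(lib, "P2"))
  oracle <- bruteForceScreen(lib, 0.56, "arithmetic")
  expect_false(any(grepl("P1:f1_1", oracle$combos)))
})

test_that("screening is deterministic: identical inputs give identical reports", {
  set.seed(64)
  lib <- randomLibrary()
  cfg <- screenConfig(0.35, "wrms")
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeReport(screenFragments(lib, cfg), f1, "json")
  writeReport(screenFragments(lib, cfg), f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reported combinations can be capped without touching classification", {
  lib <- libraryFromLes(list(c(0.5, 0.45, 0.4), c(0.5, 0.45, 0.4)))
  full <- screenFragments(lib, screenConfig(0.4))
  capped <- screenFragments(lib, screenConfig(0.4, maxCombinationsReported = 2))
  expect_equal(nrow(accepted(capped)), 2)
  expect_identical(accepted(capped), accepted(full)[1:2, ])
  expect_identical(classification(capped), classification(full))
  expect_equal(screenStats(capped)$accepted_total,
               screenStats(full)$accepted_total)
})

test_that("classical per-fragment triage ignores partners", {
  lib <- libraryFromLes(list(c(0.5, 0.3), c(0.5, 0.3)))
  cls <- classicSelection(lib, screenConfig(0.4))
  expect_equal(unname(cls[c("P1:f1_1", "P1:f1_2")]), c("selected", "rejected"))
  # the RGC screen rescues what the classical screen throws away
  rgc <- classification(screenFragments(lib, screenConfig(0.4)))
  expect_identical(unname(rgc["P1:f1_2"]), "rescued")
})
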