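test_that("edi follows the shifted-ratio rule with its floor", {
  expect_equal(edi(1e9, 2e10), 1.05)
  expect_equal(edi(0, 5e9), 1)
  expect_error(edi(1e9, 0), "positive")
  expect_error(edi(-1, 1e9), "non-negative")
  # always >= 1
  set.seed(81)
  expect_true(all(edi(runif(50, 0, 1e10), runif(50, 1e9, 1e12)) >= 1))
})

test_that("hhi matches hand-computed concentration values", {
  mk <- function(values) flows_from_edges(data.frame(
    exporter = sprintf("S%d", seq_along(values)), importer = "IMP",
    value = values))
  expect_equal(hhi(mk(7e8), "IMP", 2019), 1)               # sole supplier
  expect_equal(hhi(mk(rep(1e8, 4)), "IMP", 2019), 0.25)    # K equal -> 1/K
  expect_equal(hhi(mk(c(5, 3, 2) * 1e8), "IMP", 2019), 0.38)
  expect_error(hhi(mk(1e8), "GHO", 2019), "no positive imports")
})

test_that("rici weights supplier risk by import shares", {
  fl <- flows_from_edges(data.frame(exporter = c("AAA", "BBB"),
                                    importer = "IMP",
                                    value = c(6e8, 4e8)))
  ind <- data.frame(iso3 = c("AAA", "BBB", "IMP"), year = 2019,
                    gdp_usd = 1e11, cri = c(2, 5, 7.3))
  expect_equal(rici(fl, ind, "IMP", 2019), 0.6 * 2 + 0.4 * 5)
  # degenerate literal mode: importer's own index, shares ignored
  expect_equal(rici(fl, ind, "IMP", 2019, mode = "own_cri"), 7.3)
  # all CRI equal passes through exactly
  ind$cri <- 1
  expect_identical(rici(fl, ind, "IMP", 2019), 1)
  # missing CRI names the offenders
  ind2 <- ind[ind$iso3 != "BBB", ]
  expect_error(rici(fl, ind2, "IMP", 2019), "BBB")
})

test_that("rici stays inside the supplier CRI envelope", {
  set.seed(91)
  for (rep in 1:10) {
    ns <- sample(2:6, 1)
    sup <- sprintf("S%d", seq_len(ns))
    fl <- flows_from_edges(data.frame(exporter = sup, importer = "IMP",
                                      value = runif(ns, 1e7, 1e9)))
    ind <- data.frame(iso3 = c(sup, "IMP"), year = 2019, gdp_usd = 1e11,
                      cri = c(runif(ns, 1, 100), 1))
    r <- rici(fl, ind, "IMP", 2019)
    expect_gte(r, min(ind$cri[seq_len(ns)]))
    expect_lte(r, max(ind$cri[seq_len(ns)]))
  }
})

test_that("aecsi composes components and contribution rates", {
  a <- aecsi(1.05, 0.38, 1.0)
  expect_equal(a$aecsi, 2.43)
  expect_equal(unname(a$cr), c(1.05, 0.38, 1.0) / 2.43, tolerance = 1e-12)
  expect_equal(sum(a$cr), 1, tolerance = 1e-12)

  sym <- aecsi(1, 1, 1)
  expect_equal(sym$aecsi, 3)
  expect_true(all(sym$cr == 1 / 3))

  g <- aecsi(mode = "graded", grades = c(2, 3, 5))
  expect_equal(g$aecsi, 10)

  expect_error(aecsi(0, 0, 0), "undefined")

  # additivity in raw mode
  base <- aecsi(1.2, 0.5, 2)$aecsi
  expect_equal(aecsi(1.2, 0.5, 4)$aecsi - base, 2)
})

test_that("dominant risk needs a strict majority contributor", {
  expect_equal(dominant_risk(0.43, 0.16, 0.41), "Compound risks")
  cr <- c(1, 1, 10) / 12
  expect_equal(dominant_risk(cr[1], cr[2], cr[3]), "RICI risk")
  expect_equal(dominant_risk(0.5, 0.25, 0.25), "Compound risks")
  expect_equal(dominant_risk(0.6, 0.2, 0.2), "EDI risk")
  expect_equal(dominant_risk(0.2, 0.6, 0.2), "HHI risk")
})

test_that("risk_pipeline scores a pre-epidemic world coherently", {
  w <- generate_world(world_config(n_countries = 40, seed = 17))
  rk <- risk_pipeline(w$flows, w$indicators, 2019)
  expect_true(all(rk$r_rici == 1))
  expect_true(all(rk$r_edi >= 1))
  expect_true(all(rk$r_hhi > 0 & rk$r_hhi <= 1))
  expect_equal(rk$cr_edi + rk$cr_hhi + rk$cr_rici, rep(1, nrow(rk)),
               tolerance = 1e-12)
  expect_equal(rk$aecsi, rk$r_edi + rk$r_hhi + rk$r_rici)
  # with EDI >= 1 and RICI = 1, RICI can never contribute > 1/2
  expect_false(any(rk$dominant == "RICI risk"))
  # RICI cross-section is constant, flagged degenerate, graded lowest
  expect_true("rici" %in% names(attr(rk, "degenerate")))
  expect_true(all(rk$grade_rici == 1L))
  cfg <- attr(rk, "config")
  expect_equal(cfg$classifier, "jenks")
  expect_equal(attr(rk, "breaks")$aecsi$method, "equal_interval")
})

test_that("risk_pipeline isolates per-country failures", {
  # one country reports an unusable GDP: its EDI fails, everyone else is
  # scored (its CRI is still there, so partner-weighted RICI is unaffected)
  w <- generate_world(world_config(n_countries = 20, seed = 23))
  ind <- w$indicators
  broken <- ind$iso3[1]
  ind$gdp_usd[1] <- 0
  rk <- risk_pipeline(w$flows, ind, 2019)
  expect_false(broken %in% rk$country)
  expect_true(broken %in% names(attr(rk, "failures")))
  expect_match(attr(rk, "failures")[[broken]], "gdp")
  expect_equal(nrow(rk), 19L)

  # a missing indicator row cascades: that country is also everyone's
  # supplier here, so partner CRIs go missing and the whole year fails loud
  expect_error(risk_pipeline(w$flows, w$indicators[-1, ], 2019),
               "no country could be scored")
})

test_that("graded aecsi mode sums the equal-interval component scores", {
  w <- generate_world(world_config(n_countries = 40, cri_regime = "epidemic",
                                   seed = 29), year = 2021)
  rk <- risk_pipeline(w$flows, w$indicators, 2021, aecsi_mode = "graded",
                      classifier = "equal_interval")
  expect_true(all(rk$aecsi == rk$grade_edi + rk$grade_hhi + rk$grade_rici))
  expect_true(all(rk$aecsi >= 3 & rk$aecsi <= 15))
})
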