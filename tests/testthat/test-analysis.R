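# Toy panel used throughout: TF1 binds AAAAAAAA and AAAAAAAC, all other
# factors bind nothing; G-rich URRs are binder-free.
analysis_panel <- function() {
  toy_panel(binders = list(`1` = c(AAAAAAAA = 1, AAAAAAAC = 0.3)))
}

test_that("classify_mutation implements the event decision tree", {
  panel <- analysis_panel()
  urrs <- rep(g_urr(30), 10)
  urrs[3] <- paste0("TTTT", "AAAAAAAA", "TTTT", g_urr(14))
  g <- toy_genotype(urrs)

  # mutation far from any site, creating nothing -> silent
  ev <- classify_mutation(g, list(gene = 3, position = 20, new_base = "C"),
                          panel)
  expect_identical(ev$category, "silent")
  expect_true(all(ev$components == 0))
  expect_true(all(ev$w_delta == 0))

  # last base of the site A -> C: AAAAAAAC still binds -> preserved
  ev <- classify_mutation(g, list(gene = 3, position = 11, new_base = "C",
                                  old_base = "A"), panel)
  expect_identical(ev$category, "preserved")
  expect_identical(unname(ev$components["preserved"]), 1L)
  expect_equal(ev$w_delta[1], 0.3 - 1)

  # last base A -> G: no binder remains for the only input -> deleted_unique
  ev <- classify_mutation(g, list(gene = 3, position = 11, new_base = "G"),
                          panel)
  expect_identical(ev$category, "deleted_unique")

  # creation of a new input: G-only URR gains AAAAAAAA
  urrs2 <- rep(g_urr(30), 10)
  urrs2[4] <- paste0("TTTT", "AAAAAAAG", "TTTT", g_urr(14))
  g2 <- toy_genotype(urrs2)
  ev <- classify_mutation(g2, list(gene = 4, position = 11, new_base = "A"),
                          panel)
  expect_identical(ev$category, "created_unique")

  # redundant deletion: two copies of the site, one destroyed
  urrs3 <- rep(g_urr(30), 10)
  urrs3[5] <- paste0("AAAAAAAA", "TT", "AAAAAAAA", g_urr(12))
  g3 <- toy_genotype(urrs3)
  ev <- classify_mutation(g3, list(gene = 5, position = 0, new_base = "G"),
                          panel)
  expect_identical(ev$category, "deleted_redundant")

  # combined: a middle mutation of AAAAAAAAA kills both overlapping sites
  urrs4 <- rep(g_urr(30), 10)
  urrs4[6] <- paste0("AAAAAAAAA", g_urr(21))
  g4 <- toy_genotype(urrs4)
  ev <- classify_mutation(g4, list(gene = 6, position = 4, new_base = "G"),
                          panel)
  expect_identical(ev$category, "combined")
  expect_identical(unname(ev$components["deleted_unique"]), 2L)

  expect_error(classify_mutation(g, list(gene = 3, position = 99,
                                         new_base = "A"), panel),
               "position")
  expect_error(classify_mutation(g, list(gene = 3, position = 20,
                                         new_base = "G"), panel),
               "equals")
})

test_that("event tables are normalized and silent effects are exactly zero", {
  panel <- test_panel()
  cfg <- sim_config(L = 50, M = 10, seed = 2)
  set.seed(61)
  founder <- make_founder(cfg, panel)
  et <- event_table(rep(list(founder), 5), panel, n_mut = 60)
  expect_equal(sum(et$f), 1)
  expect_true(et$f_S >= 0 && et$f_S <= 1)
  expect_identical(et$n_probes, 300L)
  expect_identical(unname(et$e["silent"]), 0)
  expect_true(all(et$e[!is.na(et$e)] >= 0))

  # binder-free population: everything is silent
  p0 <- toy_panel()
  g0 <- toy_genotype(rep(g_urr(50), 10))
  et0 <- event_table(g0, p0, n_mut = 50)
  expect_equal(unname(et0$f["silent"]), 1)
  expect_equal(et0$f_S, 1)
  expect_equal(et0$mean_distance, 0)
})

test_that("robustness decomposition matches hand-computed arithmetic", {
  mk <- function(f, e, f_S = 1) {
    ff <- stats::setNames(numeric(7), EVENT_CATEGORIES)
    ee <- stats::setNames(rep(NA_real_, 7), EVENT_CATEGORIES)
    ff[names(f)] <- f
    ee[names(e)] <- e
    structure(list(f = ff, e = ee, f_S = f_S), class = "event_table")
  }
  # two active categories; spreadsheet arithmetic:
  # rho_silent = 0, rho_du = 0.2*0.5 - 0.1*0.3 = 0.07
  # rho'_du = (0.2 - 0.1)*0.5 = 0.05; delta_g_du = -0.2 < 0
  # CS = (0.07 - 0.05) / 0.07 = 0.285714...
  init <- mk(c(silent = 0.5, deleted_unique = 0.5),
             c(silent = 0, deleted_unique = 0.2))
  fin <- mk(c(silent = 0.7, deleted_unique = 0.3),
            c(silent = 0, deleted_unique = 0.1))
  d <- decompose_robustness(init, fin)
  expect_equal(d$cs, 0.2857142857, tolerance = 1e-9)
  expect_equal(sum(d$delta_g), 0)
  expect_equal(unname(d$rho["deleted_unique"]), 0.07)
  expect_equal(unname(d$rho_prime["deleted_unique"]), 0.05)

  # frequencies unchanged, effects shrink -> CS = 0
  fin2 <- mk(c(silent = 0.5, deleted_unique = 0.5),
             c(silent = 0, deleted_unique = 0.1))
  expect_equal(decompose_robustness(init, fin2)$cs, 0)

  # no change at all -> undefined
  expect_error(decompose_robustness(init, init), "undefined")
})

test_that("frequency changes conserve mass in real probe data", {
  panel <- test_panel()
  cfg <- sim_config(L = 50, M = 10, seed = 3)
  set.seed(67)
  f1 <- make_founder(cfg, panel)
  f2 <- make_founder(cfg, panel)
  et1 <- event_table(f1, panel, n_mut = 400)
  et2 <- event_table(f2, panel, n_mut = 400)
  expect_equal(sum(et1$f), 1, tolerance = 1e-12)
  expect_equal(sum(et2$f - et1$f), 0, tolerance = 1e-9)
})

test_that("tfbs_avoidance is the silent frequency over the free fraction", {
  et <- structure(list(f = c(silent = 0.5)), class = "event_table")
  expect_equal(tfbs_avoidance(et, 0.5), 1)
  expect_equal(tfbs_avoidance(structure(list(f = c(silent = 0.9)),
                                        class = "event_table"), 0.6), 1.5)
  expect_error(tfbs_avoidance(et, 0), "positive")
})

test_that("de novo propensity enumerates binder-creating mutants", {
  # 6 of the 24 mutants of GGGGGGGG are binders -> 0.25
  six <- c("AGGGGGGG", "CGGGGGGG", "TGGGGGGG",
           "GAGGGGGG", "GCGGGGGG", "GTGGGGGG")
  panel <- toy_panel(n = 2,
                     binders = list(`1` = stats::setNames(rep(0.5, 6), six)))
  g <- new_genotype(c("GGGGGGGG", "GGGGGGGG"), c(1L, 1L), c(1, 1))
  net <- build_network(g, panel)
  expect_equal(de_novo_propensity(g, net, panel), 0.25)

  # empty tables -> 0
  p0 <- toy_panel(n = 2)
  expect_equal(de_novo_propensity(g, build_network(g, p0), p0), 0)

  # no free window -> NA with warning
  pfull <- toy_panel(n = 2, binders = list(`1` = c(GGGGGGGG = 1)))
  netf <- build_network(g, pfull)
  expect_warning(v <- de_novo_propensity(g, netf, pfull), "free")
  expect_true(is.na(v))
})

test_that("rewiring matches brute-force set arithmetic", {
  a <- matrix(0, 10, 10); a[1, 1] <- 1; a[2, 2] <- 1; a[3, 3] <- 1
  b <- matrix(0, 10, 10); b[1, 1] <- 2
  expect_equal(rewiring_phi(a, a), 0)
  expect_equal(rewiring_phi(a, b), 2 / 3)
  disj <- matrix(0, 10, 10); disj[4, 4] <- 1
  expect_equal(rewiring_phi(a, disj), 1)
  expect_equal(rewiring_phi(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_error(rewiring_phi(a, matrix(0, 3, 3)), "dimension")

  set.seed(71)
  ok <- vapply(1:1000, function(r) {
    pa <- matrix(stats::runif(25) < 0.3, 5, 5)
    pb <- matrix(stats::runif(25) < 0.3, 5, 5)
    ia <- which(pa); ib <- which(pb)
    expected <- if (length(union(ia, ib)) == 0) 0 else
      1 - length(intersect(ia, ib)) / length(union(ia, ib))
    got <- rewiring_phi(pa * 1, pb * 1)
    isTRUE(all.equal(got, expected)) && got >= 0 && got <= 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("phi correction rescales against the chance baseline", {
  base <- structure(list(a = 0.6, b = 0), class = "phi_baseline")
  expect_equal(phi_corrected(0.6, 0.2, base), 0)
  expect_equal(phi_corrected(1, 0.2, base), 1)
  expect_equal(phi_corrected(0.8, 0.2, base), 0.5)
  bad <- structure(list(a = 1.0, b = 0.5), class = "phi_baseline")
  expect_error(phi_corrected(0.8, 0.2, bad), "baseline")
})

test_that("the random-rewiring baseline is a least-squares line", {
  panel <- test_panel()
  cfg <- sim_config(L = 50, M = 10, seed = 4)
  set.seed(73)
  base <- phi_random_baseline(c(0.15, 0.45), panel, cfg, n_pairs = 12)
  expect_true(is.finite(base$a) && is.finite(base$b))
  expect_true(base$r_squared >= 0 && base$r_squared <= 1)
  # two-point grid: the line interpolates the per-target means exactly
  m1 <- mean(base$points$phi[base$points$target == 0.15])
  m2 <- mean(base$points$phi[base$points$target == 0.45])
  expect_equal(base$a + base$b * 0.15, m1, tolerance = 1e-9)
  expect_equal(base$a + base$b * 0.45, m2, tolerance = 1e-9)
  # denser networks share more chance connections: phi decreases
  expect_lt(m2, m1)
  expect_true(all(base$points$phi >= 0 & base$points$phi <= 1))
})

test_that("redundancy correction is centred on the random ensemble", {
  panel <- test_panel()
  cfg <- sim_config(L = 50, M = 10, seed = 5)
  set.seed(79)
  f <- make_founder(cfg, panel)
  nr <- net_redundancy(f, panel, cfg, n_random = 80)
  expect_gte(nr$raw, 0)
  expect_equal(nr$raw - nr$baseline_mean, nr$corrected)
  # the founder is itself a random viable genotype at L = 50; its
  # corrected redundancy should sit within a few SE of zero
  expect_lt(abs(nr$corrected), 6)
})

test_that("mean TFBS conservation averages per-site mutant survival", {
  site <- "ACGTACGT"
  half <- single_point_mutants(site)[1:12]
  panel <- toy_panel(n = 2, binders = list(
    `1` = stats::setNames(c(1, rep(0.5, 12)), c(site, half))))
  g <- new_genotype(c(site, "GGGGGGGG"), c(1L, 1L), c(1, 1))
  ind <- list(genotype = g,
              scans = lapply(g$urrs, cisnet:::scan_codes,
                             km = cisnet:::kappa_matrix(panel)),
              w = matrix(c(1, 0, 0, 0), 2, 2),
              result = list(stable = TRUE, phenotype = c(1, 0.5)))
  expect_equal(mean_tfbs_conservation(ind, panel), 0.5)

  g0 <- new_genotype(c("GGGGGGGG", "GGGGGGGG"), c(1L, 1L), c(1, 1))
  ind0 <- list(genotype = g0,
               scans = lapply(g0$urrs, cisnet:::scan_codes,
                              km = cisnet:::kappa_matrix(panel)),
               w = matrix(0, 2, 2),
               result = list(stable = TRUE, phenotype = c(0.5, 0.5)))
  expect_warning(v <- mean_tfbs_conservation(ind0, panel), "no annotated")
  expect_true(is.na(v))
})

test_that("measure_robustness averages stable-probe distances", {
  # binder-free world: every probe is silent, distance exactly 0
  p0 <- toy_panel()
  g0 <- toy_genotype(rep(g_urr(50), 10), initial_state = rep(0, 10))
  r <- measure_robustness(g0, p0, n_mut = 40)
  expect_equal(r$mean_distance, 0)
  expect_equal(r$fraction_stable, 1)

  panel <- test_panel()
  cfg <- sim_config(L = 50, M = 10, seed = 6)
  set.seed(83)
  f <- make_founder(cfg, panel)
  r <- measure_robustness(f, panel, n_mut = 200)
  expect_true(r$fraction_stable >= 0 && r$fraction_stable <= 1)
  expect_gte(r$mean_distance, 0)
})

test_that("combined events mirror the single-event spectrum", {
  panel <- test_panel()
  cfg <- sim_config(L = 100, M = 10, seed = 8)
  set.seed(89)
  f <- make_founder(cfg, panel)
  et <- event_table(rep(list(f), 4), panel, n_mut = 500)
  singles <- et$counts[c("preserved", "deleted_unique", "deleted_redundant",
                         "created_unique", "created_redundant")]
  comps <- et$combined_components
  expect_identical(names(comps), names(singles))
  if (sum(comps) > 10 && sum(singles) > 10) {
    ct <- suppressWarnings(cor.test(as.numeric(singles), as.numeric(comps),
                                    method = "spearman"))
    expect_gt(ct$estimate, 0)
  }
})
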