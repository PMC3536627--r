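test_that("generated landscapes enumerate all 8-mers, deterministically", {
  params <- landscape_params(n_binders = 300, seed = 123)
  raw <- generate_raw_landscape(params)
  expect_length(raw$epsilon, 65536)
  expect_true(all(is.finite(raw$epsilon)))

  raw2 <- generate_raw_landscape(params)
  expect_identical(raw$epsilon, raw2$epsilon)

  expect_error(landscape_params(n_binders = 0), "n_binders")
  expect_error(landscape_params(n_binders = 65536), "n_binders")
})

test_that("binder count is calibrated exactly (brute-force oracle)", {
  for (nb in c(60, 300, 900)) {
    raw <- generate_raw_landscape(landscape_params(n_binders = nb,
                                                   seed = nb))
    # independent recount straight from raw scores
    eps <- raw$epsilon
    ep <- (max(eps) - eps) / (max(eps) - min(eps))
    expect_identical(sum(ep >= 0.209), as.integer(nb))
    tab <- specificity(normalize(raw), gamma = 0.05)
    expect_identical(tab$binder_count, as.integer(nb))
  }
})

test_that("normalization is anchored at the consensus and linear", {
  eps <- c(-5, seq(0, 10, length.out = 65535))
  raw <- structure(list(tf_id = "toy", epsilon = eps),
                   class = "raw_landscape")
  norm <- normalize(raw)
  expect_equal(norm$eprime[which.min(eps)], 1)
  expect_equal(norm$eprime[which.max(eps)], 0)
  expect_equal(norm$consensus, 1L)
  # halfway score -> 0.5
  mid <- structure(list(tf_id = "toy",
                        epsilon = c(0, 2, rep(4, 65534))),
                   class = "raw_landscape")
  expect_equal(normalize(mid)$eprime[2], 0.5)
  # order-reversing
  expect_true(all(diff(norm$eprime[order(eps)]) <= 0))

  degen <- structure(list(tf_id = "toy", epsilon = rep(1, 65536)),
                     class = "raw_landscape")
  expect_error(normalize(degen), "degenerate")
})

test_that("lambda and gamma are linked through the binder threshold", {
  # frozen values from independent evaluation of log(gamma)/(eprime_opt-1)
  expect_equal(lambda_from_gamma(0.05, 0.209), 3.78727215367, tolerance = 1e-10)
  expect_equal(lambda_from_gamma(0.20, 0.209), 2.03468762634, tolerance = 1e-10)
  expect_lt(lambda_from_gamma(0.999999), 1e-5) # gamma -> 1 limit
  expect_error(lambda_from_gamma(0), "gamma")
  expect_error(lambda_from_gamma(1.2), "gamma")
  expect_error(lambda_from_gamma(0.05, 1.5), "eprime_opt")
})

test_that("specificity transform hits its anchors and cutoff", {
  ls <- test_single_landscape()
  tab <- ls$table
  ep <- ls$norm$eprime
  # consensus kappa exactly 1
  expect_identical(tab$kappa[ls$norm$consensus], 1)
  # all binders in [gamma-ish, 1]; below cutoff exactly 0
  expect_true(all(tab$kappa[tab$binders] >= tab$gamma - 1e-12))
  expect_true(all(tab$kappa[-tab$binders] == 0))
  expect_true(all(ep[tab$binders] >= 0.209))
  expect_true(all(ep[-tab$binders] < 0.209))
  # closed form on the binder set
  expect_equal(tab$kappa[tab$binders],
               exp(tab$lambda * (ep[tab$binders] - 1)))
  # kappa at the threshold equals gamma by construction of lambda
  expect_equal(exp(tab$lambda * (0.209 - 1)), 0.05, tolerance = 1e-12)
})

test_that("binder set is invariant across gamma; kappa monotone", {
  ls <- test_single_landscape()
  tabs <- lapply(c(0.05, 0.10, 0.20), function(g)
    specificity(ls$norm, gamma = g))
  expect_identical(tabs[[1]]$binders, tabs[[2]]$binders)
  expect_identical(tabs[[2]]$binders, tabs[[3]]$binders)
  # strictly increasing in eprime on the binder set
  b <- tabs[[1]]$binders
  ord <- order(ls$norm$eprime[b])
  expect_true(all(diff(tabs[[1]]$kappa[b][ord]) > 0))
  # for fixed eprime < 1, kappa increases with gamma
  weak <- b[which.min(ls$norm$eprime[b])]
  kappas <- vapply(tabs, function(t) t$kappa[weak], numeric(1))
  expect_true(all(diff(kappas) > 0))
})

test_that("tfbs_conservation counts binding mutants", {
  tab <- specificity_from_binders(c(AAAAAAAA = 1, AAAAAAAC = 0.4))
  expect_equal(tfbs_conservation("AAAAAAAA", tab), 1 / 24)
  expect_equal(tfbs_conservation("AAAAAAAC", tab), 1 / 24)
  expect_error(tfbs_conservation("GGGGGGGG", tab), "not a binder")

  # full / empty fractions
  site <- "ACGTACGT"
  full <- specificity_from_binders(
    stats::setNames(rep(0.5, 25), c(site, single_point_mutants(site))))
  expect_equal(tfbs_conservation(site, full), 1)
  lone <- specificity_from_binders(stats::setNames(1, site))
  expect_equal(tfbs_conservation(site, lone), 0)
})

test_that("stronger sites are more mutation-resistant on additive landscapes", {
  ls <- test_single_landscape(n_binders = 300, epistasis_weight = 0,
                              seed = 99)
  tab <- ls$table
  cons <- cisnet:::conservation_by_index(tab$binders, tab)
  ct <- suppressWarnings(
    cor.test(tab$kappa[tab$binders], cons, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("default panel calibration stays in the 60-900 site range", {
  panel <- test_panel()
  expect_length(panel$tables, 10)
  counts <- vapply(panel$tables, `[[`, integer(1), "binder_count")
  expect_true(all(counts >= 60 & counts <= 900))
  # regeneration with the same seed is identical
  panel2 <- generate_landscape_panel(n_tf = 10, gamma = 0.05, seed = 42)
  expect_identical(panel$tables[[3]]$kappa, panel2$tables[[3]]$kappa)
})

test_that("landscape TSV round-trips at full precision", {
  panel <- test_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(panel_landscape(panel, 1), path)
  back <- read_landscape(path, tf_id = "TF1")
  expect_equal(back$raw$epsilon, panel$raw[[1]]$epsilon)
  expect_equal(back$norm$eprime, panel$norm[[1]]$eprime)
  expect_equal(back$table$kappa, panel$tables[[1]]$kappa)
  # recovered gap = kappa of the weakest binder, slightly above nominal
  expect_equal(back$table$gamma, panel$gamma, tolerance = 1e-3)
  expect_identical(back$table$binders, panel$tables[[1]]$binders)

  # format violations (base-R edits to avoid data.table [ semantics)
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "numeric", "numeric"))
  rewrite <- function(x) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rewrite(df[-1, ])
  expect_error(read_landscape(path), "rows")
  df2 <- df
  df2$kmer[2] <- df2$kmer[1]
  rewrite(df2)
  expect_error(read_landscape(path), "duplicate")
  rewrite(df[, setdiff(names(df), "kappa")])
  expect_error(read_landscape(path), "kappa")
})
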