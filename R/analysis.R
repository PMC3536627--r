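# Measurement suite: robustness probing, mutation-event classification
# (decision tree over site-annotation diffs), robustness decomposition,
# TFBS conservation/avoidance, de-novo site propensity, redundancy
# correction, and network rewiring with its random-network baseline.

#' Mutation-event categories
#'
#' Every point mutation in a URR maps to exactly one category: `silent`
#' (no site affected), `preserved` (a site persists, possibly with a new
#' specificity), deletion or creation of a site (`_unique` when the
#' (gene, factor) input is lost/established, `_redundant` otherwise), or
#' `combined` (two or more elementary changes at once).
#' @export
EVENT_CATEGORIES <- c("silent", "preserved", "deleted_unique",
                      "deleted_redundant", "created_unique",
                      "created_redundant", "combined")

ELEMENTARY_CATEGORIES <- c("preserved", "deleted_unique",
                           "deleted_redundant", "created_unique",
                           "created_redundant")

# Classify the consequences of substituting base `newb` (code 0..3) at
# 1-based position p of the coded URR. tf_counts: per-factor site counts
# in the URR before the mutation. Returns the category, the elementary
# event tallies and the increment to the gene's w row.
probe_core <- function(codes, p, newb, km, tf_counts) {
  L <- length(codes)
  n_tf <- ncol(km)
  aff_lo <- max(0L, p - KMER_LEN)        # 0-based window offsets
  aff_hi <- min(L - KMER_LEN, p - 1L)
  seg <- codes[(aff_lo + 1L):(aff_hi + KMER_LEN)]
  ib <- window_indices(seg)
  seg[p - aff_lo] <- newb
  ia <- window_indices(seg)
  kb <- km[ib, , drop = FALSE]
  ka <- km[ia, , drop = FALSE]

  del <- kb > 0 & ka == 0
  crea <- kb == 0 & ka > 0
  pres <- kb > 0 & ka > 0
  n_del <- sum(del)
  n_crea <- sum(crea)
  n_pres <- sum(pres)
  n_events <- n_del + n_crea + n_pres

  w_delta <- colSums(ka) - colSums(kb)

  comp <- c(preserved = n_pres, deleted_unique = 0L,
            deleted_redundant = 0L, created_unique = 0L,
            created_redundant = 0L)
  if (n_del + n_crea > 0L) {
    nr <- nrow(kb)
    del_tf <- tabulate(((which(del) - 1L) %/% nr) + 1L, n_tf)
    crea_tf <- tabulate(((which(crea) - 1L) %/% nr) + 1L, n_tf)
    counts_after <- tf_counts - del_tf + crea_tf
    comp["deleted_unique"] <- sum(del_tf[counts_after == 0L])
    comp["deleted_redundant"] <- n_del - comp["deleted_unique"]
    comp["created_unique"] <- sum(crea_tf[tf_counts == 0L])
    comp["created_redundant"] <- n_crea - comp["created_unique"]
  }

  category <- if (n_events == 0L) {
    "silent"
  } else if (n_events == 1L) {
    ELEMENTARY_CATEGORIES[which(comp > 0L)[1]]
  } else {
    "combined"
  }
  list(category = category, components = comp, w_delta = w_delta)
}

#' Classify a point mutation by its effect on binding-site annotations
#'
#' Diffs the site annotations of the affected URR before and after the
#' mutation (only windows overlapping the mutated base can change). A
#' deletion is `unique` when no site for that (gene, factor) input
#' remains afterwards; a creation is `unique` when the input did not
#' exist before. A site present on both sides is `preserved` (its kappa
#' may have changed). No elementary change at all is `silent`; two or
#' more are `combined`.
#'
#' @param genotype A `genotype`.
#' @param mutation List or one-row data.frame with `gene` (1-based
#'   index), `position` (0-based offset in the URR), `new_base`, and
#'   optionally `old_base` (validated when present).
#' @param panel A `landscape_panel`.
#' @return Object of class `mutation_event`: `category`, `components`
#'   (named tally of elementary events), `w_delta` (increment to the
#'   affected w row).
#' @export
classify_mutation <- function(genotype, mutation, panel) {
  panel <- prime_panel(as_panel(panel))
  km <- attr(panel, "kappa_matrix")
  g <- as.integer(mutation$gene)
  pos <- as.integer(mutation$position)
  if (g < 1L || g > genotype$n) stop("gene index out of range")
  if (pos < 0L || pos >= genotype$L) stop("position out of range")
  codes <- genotype$urrs[[g]]
  newb <- dna_to_codes(as.character(mutation$new_base))
  if (!is.null(mutation$old_base)) {
    old <- dna_to_codes(as.character(mutation$old_base))
    if (codes[pos + 1L] != old) {
      stop("old_base does not match the genotype at that position")
    }
  }
  if (codes[pos + 1L] == newb) stop("new_base equals the current base")
  sc <- scan_codes(codes, km)
  res <- probe_core(codes, pos + 1L, newb, km,
                    tabulate(sc$tf, ncol(km)))
  structure(res, class = "mutation_event")
}

as_individual <- function(x, panel, params) {
  if (is.list(x) && !is.null(x$scans) && !is.null(x$result)) return(x)
  if (inherits(x, "genotype")) {
    ind <- make_individual(x, panel, params)
    if (!ind$result$stable) stop("individual is not viable (unstable)")
    return(ind)
  }
  stop("expected a simulated individual or a genotype")
}

# Run n_mut uniform random single-point-mutation probes on one
# individual. Returns category, stability and phenotype distance per
# probe, plus pooled elementary-component tallies of combined probes.
probe_individual <- function(ind, panel, n_mut, params) {
  km <- attr(panel, "kappa_matrix")
  n <- ind$genotype$n
  L <- ind$genotype$L
  n_tf <- ncol(km)
  tf_counts <- lapply(ind$scans, function(sc) tabulate(sc$tf, n_tf))
  base_phen <- ind$result$phenotype
  signs <- ind$genotype$tf_signs
  init <- ind$genotype$initial_state

  genes <- sample.int(n, n_mut, replace = TRUE)
  poss <- sample.int(L, n_mut, replace = TRUE)
  deltas <- sample.int(3L, n_mut, replace = TRUE)

  category <- character(n_mut)
  stable <- logical(n_mut)
  distance <- rep(NA_real_, n_mut)
  comp_combined <- stats::setNames(numeric(5L), ELEMENTARY_CATEGORIES)

  for (k in seq_len(n_mut)) {
    g <- genes[k]
    p <- poss[k]
    codes <- ind$genotype$urrs[[g]]
    newb <- (codes[p] + deltas[k]) %% 4L
    pr <- probe_core(codes, p, newb, km, tf_counts[[g]])
    category[k] <- pr$category
    if (pr$category == "combined") {
      comp_combined <- comp_combined + pr$components
    }
    if (all(pr$w_delta == 0)) {
      stable[k] <- TRUE
      distance[k] <- 0
      next
    }
    w2 <- ind$w
    w2[g, ] <- w2[g, ] + pr$w_delta
    dev <- develop_w(w2, signs, init, params)
    stable[k] <- dev$stable
    if (dev$stable) {
      distance[k] <- phenotype_distance(dev$phenotype, base_phen)
    }
  }
  list(category = category, stable = stable, distance = distance,
       comp_combined = comp_combined)
}

#' Robustness of an individual to single point mutations
#'
#' Applies `n_mut` independent uniform random point mutations (uniform
#' genome position, uniform alternative base), redevelops each mutant,
#' and averages the phenotype distance to the unperturbed phenotype over
#' the stable mutants. Unstable mutants are excluded from the average
#' but counted in the stable fraction.
#'
#' @param individual A simulated individual or a viable `genotype`.
#' @param panel A `landscape_panel`.
#' @param n_mut Number of probes (default 100).
#' @param params Dynamics parameters.
#' @return List with `mean_distance` and `fraction_stable`.
#' @export
measure_robustness <- function(individual, panel, n_mut = 100L,
                               params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  ind <- as_individual(individual, panel, params)
  pr <- probe_individual(ind, panel, n_mut, params)
  list(mean_distance = mean(pr$distance[pr$stable]),
       fraction_stable = mean(pr$stable))
}

#' Pooled mutation-event table of a population
#'
#' Pools `n_mut` probes per individual. Frequencies `f` are per-category
#' counts among stable probes, normalized to sum to 1; `e` is the mean
#' phenotype distance per category (stable probes only); `f_S` is the
#' fraction of all probes that developed stably.
#'
#' @param population A list of simulated individuals (or a single one).
#' @param panel A `landscape_panel`.
#' @param n_mut Probes per individual.
#' @param params Dynamics parameters.
#' @return Object of class `event_table`: `f`, `e`, `f_S`, `counts`,
#'   `n_probes`, `mean_distance` (robustness over all stable probes) and
#'   `combined_components` (pooled elementary tallies inside combined
#'   events).
#' @export
event_table <- function(population, panel, n_mut = 100L,
                        params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  if (!is.null(population$scans) || inherits(population, "genotype")) {
    population <- list(population)
  }
  cats <- character(0)
  stabs <- logical(0)
  dists <- numeric(0)
  comp <- stats::setNames(numeric(5L), ELEMENTARY_CATEGORIES)
  for (x in population) {
    ind <- as_individual(x, panel, params)
    pr <- probe_individual(ind, panel, n_mut, params)
    cats <- c(cats, pr$category)
    stabs <- c(stabs, pr$stable)
    dists <- c(dists, pr$distance)
    comp <- comp + pr$comp_combined
  }
  n_probes <- length(cats)
  stable_cats <- factor(cats[stabs], levels = EVENT_CATEGORIES)
  counts <- table(stable_cats)
  f <- as.numeric(counts) / sum(counts)
  names(f) <- EVENT_CATEGORIES
  e <- vapply(EVENT_CATEGORIES, function(cc) {
    d <- dists[stabs & cats == cc]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  structure(
    list(f = f, e = e, f_S = mean(stabs),
         counts = stats::setNames(as.integer(counts), EVENT_CATEGORIES),
         n_probes = n_probes,
         mean_distance = mean(dists[stabs]),
         combined_components = comp),
    class = "event_table"
  )
}

#' Decompose the robustness change into silent and other contributions
#'
#' With `g_i` the stable-normalized event frequencies (summing to 1 at
#' both endpoints), the observed per-category robustness change is
#' `rho_i = e_i^initial * g_i^initial - e_i^final * g_i^final` and the
#' constant-frequency counterfactual is
#' `rho'_i = (e_i^initial - e_i^final) * g_i^initial`. The contribution
#' of the silent-frequency shift (CS) is the summed excess
#' `rho_i - rho'_i` over the categories whose frequency decreased,
#' relative to the total observed change.
#'
#' @param initial,final `event_table`s at the two endpoints.
#' @return List with `cs`, `rho`, `rho_prime`, `delta_g`.
#' @export
decompose_robustness <- function(initial, final) {
  if (!inherits(initial, "event_table") || !inherits(final, "event_table")) {
    stop("initial and final must be event_table objects")
  }
  g0 <- initial$f
  g1 <- final$f
  e0 <- ifelse(is.na(initial$e), 0, initial$e)
  e1 <- ifelse(is.na(final$e), 0, final$e)
  rho <- e0 * g0 - e1 * g1
  rho_prime <- (e0 - e1) * g0
  total <- sum(rho)
  if (total == 0) stop("decomposition undefined: total robustness change is zero")
  dg <- g1 - g0
  cs <- sum((rho - rho_prime)[dg < 0]) / total
  list(cs = cs, rho = rho, rho_prime = rho_prime, delta_g = dg)
}

#' Silent-mutation frequency normalized by the TFBS-free fraction
#'
#' Values above 1 indicate that silent mutations are more frequent than
#' the sheer size of the TFBS-free region explains, i.e. the free
#' regions have evolved resistance to creating new sites ("TFBS
#' avoidance").
#'
#' @param event_table An `event_table`.
#' @param free_fraction TFBS-free genome fraction (see
#'   [tfbs_free_fraction()]).
#' @return Non-negative scalar.
#' @export
tfbs_avoidance <- function(event_table, free_fraction) {
  if (!is.numeric(free_fraction) || free_fraction <= 0) {
    stop("free_fraction must be positive")
  }
  unname(event_table$f["silent"] / free_fraction)
}

#' Probability of creating a binding site de novo
#'
#' Over all 8-mer windows that lie entirely in TFBS-free sequence, the
#' mean fraction of their 24 single-point mutants that are binders for
#' any factor.
#'
#' @param genotype A `genotype`.
#' @param network Its `regulatory_network`.
#' @param panel A `landscape_panel`.
#' @return Value in [0, 1]; NA (with a warning) when the genome has no
#'   fully TFBS-free window.
#' @export
de_novo_propensity <- function(genotype, network, panel) {
  panel <- prime_panel(as_panel(panel))
  any_binder <- attr(panel, "any_binder")
  nb <- mutant_index_matrix()
  L <- genotype$L
  vals <- numeric(0)
  for (i in seq_len(genotype$n)) {
    mask <- logical(L) # covered positions (1-based)
    off <- network$sites$offset[network$sites$gene == i]
    for (o in unique(off)) mask[(o + 1L):(o + KMER_LEN)] <- TRUE
    idx <- window_indices(genotype$urrs[[i]])
    for (o in 0:(L - KMER_LEN)) {
      if (!any(mask[(o + 1L):(o + KMER_LEN)])) {
        vals <- c(vals, mean(any_binder[nb[idx[o + 1L], ]]))
      }
    }
  }
  if (!length(vals)) {
    warning("no fully TFBS-free window; propensity undefined")
    return(NA_real_)
  }
  mean(vals)
}

# Jaccard complement of two nonzero patterns (logical matrices).
jaccard_complement <- function(pa, pb) {
  un <- sum(pa | pb)
  if (un == 0L) return(0)
  1 - sum(pa & pb) / un
}

#' Network rewiring between two interaction matrices
#'
#' The complement of the Jaccard overlap of the nonzero patterns:
#' `Phi = 1 - |N_F intersect N_I| / |N_F union N_I|`. Identical patterns
#' give 0; disjoint patterns give 1; two empty networks give 0 by
#' convention.
#'
#' @param net_founder,net_individual `regulatory_network`s or w
#'   matrices of equal dimension.
#' @return Value in [0, 1].
#' @export
rewiring_phi <- function(net_founder, net_individual) {
  wa <- if (inherits(net_founder, "regulatory_network")) net_founder$w else net_founder
  wb <- if (inherits(net_individual, "regulatory_network")) net_individual$w else net_individual
  if (!all(dim(wa) == dim(wb))) stop("networks differ in dimension")
  jaccard_complement(wa != 0, wb != 0)
}

# Expected connectivity of a random genotype of URR length L under a
# panel: each of the L-7 windows is a binder for factor j independently
# with probability binder_count_j / 65536.
expected_connectivity <- function(L, panel) {
  p <- vapply(panel$tables, `[[`, integer(1), "binder_count") / N_KMERS
  mean(1 - (1 - p)^(L - KMER_LEN + 1L))
}

# Smallest URR length whose expected random-genotype connectivity
# reaches the target (monotone in L).
match_L_for_connectivity <- function(target, panel, L_max = 100000L) {
  if (target <= 0) stop("target connectivity must be positive")
  if (expected_connectivity(L_max, panel) < target) {
    stop("target connectivity ", target, " unattainable below L = ", L_max)
  }
  lo <- KMER_LEN
  hi <- L_max
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (expected_connectivity(mid, panel) >= target) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Random-network rewiring baseline as a function of connectivity
#'
#' For each target connectivity, pairs of independent random viable
#' individuals are generated at the URR length whose expected
#' connectivity matches the target, and the rewiring between the two
#' networks of a pair is measured. A least-squares line of rewiring on
#' realized connectivity is returned; it quantifies how much apparent
#' rewiring two unrelated networks of that density show by chance.
#'
#' @param connectivity_grid Numeric vector (>= 2 values in (0, 1)).
#' @param panel A `landscape_panel`.
#' @param config A [sim_config()] (supplies n).
#' @param n_pairs Random viable pairs per grid point (>= 2).
#' @param params Dynamics parameters.
#' @param require_stable Require pair members to develop stably.
#' @return Object of class `phi_baseline`: `a` (intercept), `b` (slope),
#'   `r_squared`, and `points` (per-pair connectivity and rewiring).
#' @export
phi_random_baseline <- function(connectivity_grid, panel, config,
                                n_pairs = 50L,
                                params = dynamics_params(),
                                require_stable = TRUE) {
  panel <- prime_panel(as_panel(panel))
  if (length(connectivity_grid) < 2L) stop("need >= 2 grid points")
  target_c <- numeric(0)
  conn <- numeric(0)
  phi <- numeric(0)
  for (target in connectivity_grid) {
    L <- match_L_for_connectivity(target, panel)
    for (k in seq_len(n_pairs)) {
      pair <- vector("list", 2L)
      for (m in 1:2) {
        repeat {
          g <- random_genotype(config$n, L)
          ind <- make_individual(g, panel, params)
          if (!require_stable || ind$result$stable) break
        }
        pair[[m]] <- ind
      }
      target_c <- c(target_c, target)
      conn <- c(conn, (mean(pair[[1]]$w != 0) + mean(pair[[2]]$w != 0)) / 2)
      phi <- c(phi, jaccard_complement(pair[[1]]$w != 0, pair[[2]]$w != 0))
    }
  }
  fit <- stats::lm(phi ~ target_c)
  structure(
    list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         points = data.frame(target = target_c, connectivity = conn,
                             phi = phi)),
    class = "phi_baseline"
  )
}

#' Rewiring corrected for chance overlap
#'
#' Rescales raw rewiring against the random-network baseline at the
#' individual's connectivity so that chance-level rewiring maps to 0 and
#' total rewiring stays at 1; the result is clipped to [0, 1].
#'
#' @param phi_raw Raw rewiring value.
#' @param connectivity Network connectivity of the individual.
#' @param baseline A `phi_baseline` fit.
#' @return Corrected rewiring in [0, 1].
#' @export
phi_corrected <- function(phi_raw, connectivity, baseline) {
  pr <- baseline$a + baseline$b * connectivity
  if (pr >= 1) stop("invalid baseline: predicted random rewiring >= 1")
  min(1, max(0, (phi_raw - pr) / (1 - pr)))
}

#' Redundancy corrected by a random-network baseline
#'
#' Subtracts from the individual's redundant-site count the mean count
#' over random genotypes generated at the URR length whose expected
#' connectivity matches the individual's.
#'
#' @param individual A simulated individual or viable `genotype`.
#' @param panel A `landscape_panel`.
#' @param config A [sim_config()].
#' @param n_random Number of random genotypes in the baseline (>= 1).
#' @param params Dynamics parameters.
#' @return List with `raw`, `baseline_mean`, `corrected`, `matched_L`.
#' @export
net_redundancy <- function(individual, panel, config, n_random = 100L,
                           params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  ind <- as_individual(individual, panel, params)
  raw <- redundancy_count(individual_network(ind))
  target <- mean(ind$w != 0)
  L <- if (target > 0) match_L_for_connectivity(target, panel) else ind$genotype$L
  base <- vapply(seq_len(n_random), function(k) {
    g <- random_genotype(config$n, L)
    redundancy_count(build_network(g, panel))
  }, numeric(1))
  list(raw = raw, baseline_mean = mean(base), corrected = raw - mean(base),
       matched_L = L)
}

#' Mean TFBS conservation over all annotated sites of an individual
#'
#' The average probability that a binding site remains a binding site
#' for the same factor after one point mutation (fraction of the 24
#' single-point mutants of its 8-mer that still bind).
#'
#' @param individual A simulated individual or viable `genotype`.
#' @param panel A `landscape_panel`.
#' @param params Dynamics parameters (used only if a genotype must be
#'   developed).
#' @return Value in [0, 1]; NA (with warning) if there are no sites.
#' @export
mean_tfbs_conservation <- function(individual, panel,
                                   params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  ind <- as_individual(individual, panel, params)
  km <- attr(panel, "kappa_matrix")
  nb <- mutant_index_matrix()
  vals <- numeric(0)
  for (i in seq_len(ind$genotype$n)) {
    sc <- ind$scans[[i]]
    if (!length(sc$offset)) next
    idx <- window_indices(ind$genotype$urrs[[i]])
    site_idx <- idx[sc$offset + 1L]
    for (k in seq_along(site_idx)) {
      vals <- c(vals, mean(km[nb[site_idx[k], ], sc$tf[k]] > 0))
    }
  }
  if (!length(vals)) {
    warning("individual has no annotated sites; conservation undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", x$n_probes, " probes, stable fraction ",
      format(x$f_S, digits = 4), "\n", sep = "")
  m <- rbind(frequency = x$f, mean_effect = x$e)
  print(round(m, 4))
  invisible(x)
}
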