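# Population model: a viable founder defines the optimal phenotype and
# is cloned to a population of size M; each generation draws parent
# pairs with replacement, reassorts whole URRs, applies point mutations,
# and accepts offspring with probability equal to their fitness
# exp(-D(phenotype, s_opt) / sigma) until M are accepted. Unstable
# offspring have fitness zero and are always replaced.

#' Simulation configuration
#'
#' @param n Number of genes (= number of transcription factors).
#' @param L URR length in bp.
#' @param gamma Specificity gap.
#' @param M Population size.
#' @param generations Number of generations to run.
#' @param eval_interval Record a trajectory snapshot every this many
#'   generations (must divide `generations`).
#' @param sigma Strength of stabilizing selection (smaller = stronger).
#' @param mutation_rate Per-base mutation probability per generation.
#' @param robustness_mutants Number of point-mutation probes per
#'   individual when measuring robustness.
#' @param robustness_sample Number of individuals probed per snapshot
#'   (NULL = whole population). Scaled-down runs probe a subsample to
#'   keep snapshots cheap.
#' @param seed Master seed; independent streams for founder search,
#'   reproduction and robustness probing are derived from it.
#' @param founder_attempts Cap on random draws during founder search.
#' @param offspring_attempts_factor Cap on offspring draws per
#'   generation, as a multiple of M.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 10L, L = 50L, gamma = 0.05, M = 500L,
                       generations = 2000L, eval_interval = 10L,
                       sigma = 0.001, mutation_rate = 0.01,
                       robustness_mutants = 100L,
                       robustness_sample = NULL,
                       seed = NULL,
                       founder_attempts = 1e5,
                       offspring_attempts_factor = 1e3) {
  n <- as.integer(n); L <- as.integer(L); M <- as.integer(M)
  generations <- as.integer(generations)
  eval_interval <- as.integer(eval_interval)
  if (n < 1L || L < KMER_LEN || M < 1L) stop("invalid n, L or M")
  if (generations < 0L) stop("generations must be >= 0")
  if (eval_interval < 1L || (generations > 0L &&
                             generations %% eval_interval != 0L)) {
    stop("eval_interval must be positive and divide generations")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]")
  }
  structure(
    list(n = n, L = L, gamma = gamma, M = M, generations = generations,
         eval_interval = eval_interval, sigma = sigma,
         mutation_rate = mutation_rate,
         robustness_mutants = as.integer(robustness_mutants),
         robustness_sample = robustness_sample, seed = seed,
         founder_attempts = founder_attempts,
         offspring_attempts_factor = offspring_attempts_factor),
    class = "sim_config"
  )
}

# Deterministic stream seed derived from a master seed and a tag,
# kept strictly below 2^31.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 48271 + h * 69621) %% 2147483647)
}

# Internal individual: genotype + cached per-gene scans + w + result.
make_individual <- function(genotype, panel, params, fitness = NA_real_,
                            s_opt = NULL, sigma = NULL) {
  km <- kappa_matrix(panel)
  scans <- lapply(genotype$urrs, scan_codes, km = km)
  w <- do.call(rbind, lapply(scans, `[[`, "w_row"))
  result <- develop_w(w, genotype$tf_signs, genotype$initial_state, params)
  if (is.na(fitness) && !is.null(s_opt)) {
    fitness <- fitness_of(result, s_opt, sigma)
  }
  list(genotype = genotype, scans = scans, w = w, result = result,
       fitness = fitness)
}

#' Regulatory network of a simulated individual
#'
#' @param individual An individual as produced by [make_founder()] or
#'   carried in a simulation population.
#' @return A `regulatory_network`.
#' @export
individual_network <- function(individual) {
  network_from_scans(individual$scans, individual$genotype$n)
}

#' Fitness of a developed offspring
#'
#' Unstable individuals get fitness zero; stable ones
#' `exp(-D(phenotype, s_opt) / sigma)`.
#'
#' @param result A `development_result`.
#' @param s_opt Optimal phenotype (the founder's).
#' @param sigma Selection strength.
#' @return Fitness in [0, 1].
#' @export
fitness_of <- function(result, s_opt, sigma) {
  if (!result$stable) return(0)
  exp(-phenotype_distance(result$phenotype, s_opt) / sigma)
}

#' Search for a viable founder
#'
#' Draws random genotypes until one develops a stable phenotype; that
#' phenotype becomes the optimal phenotype of the simulation.
#'
#' @param config A [sim_config()].
#' @param panel A `landscape_panel` with `config$n` tables.
#' @param params Dynamics parameters.
#' @return An individual list (genotype, scans, w, result, fitness = 1)
#'   with an `attempts` field recording the number of draws.
#' @export
make_founder <- function(config, panel, params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  for (attempt in seq_len(config$founder_attempts)) {
    g <- random_genotype(config$n, config$L)
    ind <- make_individual(g, panel, params)
    if (ind$result$stable) {
      ind$fitness <- 1
      ind$attempts <- attempt
      return(ind)
    }
  }
  stop("founder search exhausted after ", config$founder_attempts,
       " attempts")
}

#' Produce the next generation
#'
#' Repeats (sample parent pair with replacement, reassort URRs, mutate,
#' develop, accept with probability = fitness) until M offspring are
#' accepted.
#'
#' @param population List of M viable individuals.
#' @param config A [sim_config()].
#' @param panel The landscape panel.
#' @param s_opt Optimal phenotype.
#' @param params Dynamics parameters.
#' @return List with `population` (the new generation) and `stats`:
#'   attempts, developed, unstable (count rejected for instability),
#'   replaced_fraction (unstable / developed), mean_fitness of accepted.
#' @export
next_generation <- function(population, config, panel, s_opt,
                            params = dynamics_params()) {
  panel <- prime_panel(as_panel(panel))
  km <- attr(panel, "kappa_matrix")
  M <- config$M
  max_attempts <- config$offspring_attempts_factor * M
  newpop <- vector("list", M)
  accepted <- 0L
  attempts <- 0L
  developed <- 0L
  unstable <- 0L
  fit_sum <- 0
  n <- config$n
  L <- config$L
  total_bp <- n * L

  while (accepted < M) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("offspring acceptance stalled after ", max_attempts,
           " attempts in one generation")
    }
    pa <- population[[sample.int(M, 1L)]]
    pb <- population[[sample.int(M, 1L)]]
    pick <- stats::runif(n) < 0.5
    urrs <- pa$genotype$urrs
    urrs[!pick] <- pb$genotype$urrs[!pick]
    scans <- pa$scans
    scans[!pick] <- pb$scans[!pick]

    # point mutations (per-base Bernoulli), rescan only mutated URRs
    hits <- which(stats::runif(total_bp) < config$mutation_rate)
    if (length(hits)) {
      gene <- ((hits - 1L) %/% L) + 1L
      pos <- (hits - 1L) %% L + 1L
      for (k in seq_along(hits)) {
        gk <- gene[k]
        urrs[[gk]][pos[k]] <- (urrs[[gk]][pos[k]] + sample.int(3L, 1L)) %% 4L
      }
      for (gk in unique(gene)) {
        scans[[gk]] <- scan_codes(urrs[[gk]], km)
      }
    }

    w <- do.call(rbind, lapply(scans, `[[`, "w_row"))
    result <- develop_w(w, pa$genotype$tf_signs, pa$genotype$initial_state,
                        params)
    developed <- developed + 1L
    if (!result$stable) {
      unstable <- unstable + 1L
      next
    }
    fitness <- exp(-phenotype_distance(result$phenotype, s_opt) /
                     config$sigma)
    if (stats::runif(1) < fitness) {
      accepted <- accepted + 1L
      g <- pa$genotype
      g$urrs <- urrs
      newpop[[accepted]] <- list(genotype = g, scans = scans, w = w,
                                 result = result, fitness = fitness)
      fit_sum <- fit_sum + fitness
    }
  }
  list(population = newpop,
       stats = list(attempts = attempts, developed = developed,
                    unstable = unstable,
                    replaced_fraction = unstable / developed,
                    mean_fitness = fit_sum / M))
}

#' Run a full simulation
#'
#' Creates a founder (or uses the one supplied), clones it to a
#' population of size M, and iterates generations; at generation 0 and
#' every `eval_interval` generations a trajectory record is appended.
#'
#' @param config A [sim_config()].
#' @param panel A `landscape_panel`.
#' @param params Dynamics parameters.
#' @param founder Optional pre-built founder individual.
#' @param record_probes If FALSE, snapshots skip the mutation-probe
#'   statistics (robustness and event table), recording only the cheap
#'   population summaries.
#' @param keep_population If TRUE the final population is returned.
#' @return Object of class `sim_result`: `records` (list of trajectory
#'   records), `founder`, `s_opt`, `config`, `replaced_history` (the
#'   per-generation fraction of developed offspring rejected as
#'   unstable), and optionally `final_population`.
#' @export
run_simulation <- function(config, panel, params = dynamics_params(),
                           founder = NULL, record_probes = TRUE,
                           keep_population = FALSE) {
  panel <- prime_panel(as_panel(panel))
  master <- if (is.null(config$seed)) {
    sample.int(.Machine$integer.max, 1)
  } else {
    config$seed
  }

  set.seed(derive_seed(master, "founder"))
  if (is.null(founder)) founder <- make_founder(config, panel, params)
  s_opt <- founder$result$phenotype
  founder_pattern <- founder$w != 0

  population <- rep(list(founder), config$M)
  records <- list()
  replaced <- NA_real_

  snapshot <- function(gen, replaced_fraction) {
    set.seed(derive_seed(master, paste0("probe", gen)))
    trajectory_record(population, panel, config, params, gen,
                      founder_pattern, replaced_fraction,
                      record_probes = record_probes)
  }

  records[[1]] <- snapshot(0L, NA_real_)
  replaced_history <- numeric(config$generations)
  if (config$generations > 0L) {
    for (gen in seq_len(config$generations)) {
      set.seed(derive_seed(master, paste0("gen", gen)))
      step <- next_generation(population, config, panel, s_opt, params)
      population <- step$population
      replaced <- step$stats$replaced_fraction
      replaced_history[gen] <- replaced
      if (gen %% config$eval_interval == 0L) {
        records[[length(records) + 1L]] <- snapshot(gen, replaced)
      }
    }
  }
  out <- list(records = records, founder = founder, s_opt = s_opt,
              config = config, seed = master,
              replaced_history = replaced_history)
  if (keep_population) out$final_population <- population
  structure(out, class = "sim_result")
}

# One trajectory record: population summaries plus (optionally) pooled
# mutation-probe statistics from a subsample of individuals.
trajectory_record <- function(population, panel, config, params, gen,
                              founder_pattern, replaced_fraction,
                              record_probes = TRUE) {
  M <- length(population)
  conn <- vapply(population, function(ind) mean(ind$w != 0), numeric(1))
  red <- vapply(population, function(ind) {
    s <- 0L
    for (sc in ind$scans) {
      if (length(sc$tf)) s <- s + length(sc$tf) - length(unique(sc$tf))
    }
    s
  }, numeric(1))
  phi <- vapply(population, function(ind) {
    jaccard_complement(founder_pattern, ind$w != 0)
  }, numeric(1))
  free <- vapply(population, function(ind) {
    free_fraction_scans(ind$scans, config$L)
  }, numeric(1))

  rec <- list(generation = gen,
              connectivity = mean(conn),
              redundancy = mean(red),
              phi_raw = mean(phi),
              free_fraction = mean(free),
              replaced_fraction = replaced_fraction,
              mean_fitness = mean(vapply(population, `[[`, numeric(1),
                                         "fitness")))
  if (record_probes) {
    idx <- seq_len(M)
    if (!is.null(config$robustness_sample) &&
        config$robustness_sample < M) {
      idx <- sample.int(M, config$robustness_sample)
    }
    et <- event_table(population[idx], panel,
                      n_mut = config$robustness_mutants, params = params)
    rec$event_table <- et
    rec$robustness <- et$mean_distance
    rec$fraction_stable <- et$f_S
  }
  rec
}

free_fraction_scans <- function(scans, L) {
  covered <- 0L
  for (sc in scans) {
    if (length(sc$offset)) {
      mask <- logical(L)
      for (o in unique(sc$offset)) mask[(o + 1L):(o + KMER_LEN)] <- TRUE
      covered <- covered + sum(mask)
    }
  }
  1 - covered / (length(scans) * L)
}

#' @export
print.sim_result <- function(x, ...) {
  first <- x$records[[1]]
  last <- x$records[[length(x$records)]]
  cat("<sim_result> ", x$config$generations, " generations, M = ",
      x$config$M, ", L = ", x$config$L, ", gamma = ", x$config$gamma,
      "\n", sep = "")
  if (!is.null(first$robustness)) {
    cat("  robustness (mean perturbation distance): ",
        format(first$robustness, digits = 4), " -> ",
        format(last$robustness, digits = 4), "\n", sep = "")
  }
  cat("  connectivity: ", format(first$connectivity, digits = 4), " -> ",
      format(last$connectivity, digits = 4), "\n", sep = "")
  invisible(x)
}
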