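# Binding landscapes: raw scores over all 65,536 8-mers, their
# normalization, and the specificity transform that defines the binder
# set of each transcription factor.
#
# Raw scores epsilon are energy-like (lower = stronger binding). The
# consensus site x(max) attains the numeric minimum; the worst site
# x(min) the numeric maximum. Normalized scores
#   eprime = (eps_min - eps) / (eps_min - eps_max)
# run from 0 (worst) to 1 (consensus). Binders are the 8-mers with
# eprime >= eprime_opt (default 0.209). On the binder set the
# specificity is kappa = exp(lambda * (eprime - 1)) with
# lambda = log(gamma) / (eprime_opt - 1), so the consensus has kappa = 1
# and the weakest binder kappa = gamma; everything below the threshold
# has kappa = 0 ("specificity gap").

#' Default normalized-score threshold defining the binder set
#' @export
EPRIME_OPT <- 0.209

#' Parameters of the synthetic landscape generator
#'
#' The generator stands in for a structure-based scoring pipeline: it
#' draws an additive per-position energy matrix (8 positions x 4 bases),
#' optionally perturbs it with pairwise epistatic terms, and finally
#' applies a monotone rescaling so that after normalization exactly
#' `n_binders` 8-mers sit at or above the `eprime_opt` threshold.
#'
#' @param n_binders Target number of binding 8-mers; the biologically
#'   calibrated range is 60 to 900 sites per factor.
#' @param additive_sd Spread of the per-position additive energy
#'   contributions (arbitrary energy units).
#' @param epistasis_weight Relative weight of pairwise inter-position
#'   energy terms (0 = purely additive landscape).
#' @param eprime_opt Normalized-score threshold defining binders.
#' @param seed Optional RNG seed for reproducible generation.
#' @param tf_id Identifier attached to the landscape.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(n_binders = 300L, additive_sd = 1,
                             epistasis_weight = 0.2,
                             eprime_opt = EPRIME_OPT,
                             seed = NULL, tf_id = "TF1") {
  n_binders <- as.integer(n_binders)
  if (is.na(n_binders) || n_binders < 1L || n_binders > N_KMERS - 1L) {
    stop("n_binders must lie in [1, ", N_KMERS - 1L, "]")
  }
  if (!is.numeric(additive_sd) || additive_sd <= 0) {
    stop("additive_sd must be positive")
  }
  if (!is.numeric(epistasis_weight) || epistasis_weight < 0) {
    stop("epistasis_weight must be non-negative")
  }
  if (eprime_opt <= 0 || eprime_opt >= 1) stop("eprime_opt must lie in (0,1)")
  structure(
    list(n_binders = n_binders, additive_sd = additive_sd,
         epistasis_weight = epistasis_weight, eprime_opt = eprime_opt,
         seed = seed, tf_id = tf_id),
    class = "landscape_params"
  )
}

#' Generate a synthetic raw binding landscape
#'
#' Scores are an additive position-energy model plus (optionally) pairwise
#' epistatic perturbations, followed by a monotone piecewise-linear
#' rescaling that pins the binder count at exactly `params$n_binders`
#' after normalization. Additivity gives the landscape correlated
#' mutational neighbourhoods: strong sites tend to have strong
#' single-point mutants, which downstream conservation statistics rely
#' on.
#'
#' @param params A [landscape_params()] object.
#' @return An object of class `raw_landscape` with fields `tf_id` and
#'   `epsilon` (numeric vector of length 65,536, indexed by 8-mer; lower
#'   = stronger binding).
#' @export
generate_raw_landscape <- function(params) {
  if (!inherits(params, "landscape_params")) {
    params <- do.call(landscape_params, as.list(params))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  dig <- kmer_digit_matrix()

  # additive position-energy matrix: 8 positions x 4 bases
  pem <- matrix(stats::rnorm(4L * KMER_LEN, sd = params$additive_sd),
                nrow = 4L, ncol = KMER_LEN)
  eps <- numeric(N_KMERS)
  for (p in seq_len(KMER_LEN)) {
    eps <- eps + pem[dig[, p] + 1L, p]
  }

  # pairwise epistatic terms, one 4x4 table per position pair
  if (params$epistasis_weight > 0) {
    sd_epi <- params$additive_sd * params$epistasis_weight
    for (p in seq_len(KMER_LEN - 1L)) {
      for (q in (p + 1L):KMER_LEN) {
        tab <- stats::rnorm(16L, sd = sd_epi)
        eps <- eps + tab[dig[, p] * 4L + dig[, q] + 1L]
      }
    }
  }

  eps <- calibrate_binder_count(eps, params$n_binders, params$eprime_opt)
  structure(list(tf_id = params$tf_id, epsilon = eps,
                 params = params),
            class = "raw_landscape")
}

# Monotone piecewise-linear rescaling of raw scores such that exactly
# n_binders 8-mers satisfy eprime >= eprime_opt after normalization.
# The knot is placed halfway between the n-th and (n+1)-th best
# normalized score, so both sides clear the threshold with a finite
# floating-point margin.
calibrate_binder_count <- function(eps, n_binders, eprime_opt) {
  lo <- min(eps)
  hi <- max(eps)
  if (hi <= lo) stop("degenerate landscape: all scores equal")
  ep0 <- (hi - eps) / (hi - lo)
  srt <- sort(ep0, decreasing = TRUE)
  q1 <- srt[n_binders]
  q2 <- srt[n_binders + 1L]
  if (q1 <= q2) stop("cannot separate binder set: tied scores at the cutoff")
  qm <- (q1 + q2) / 2
  g <- ifelse(ep0 <= qm,
              eprime_opt * ep0 / qm,
              eprime_opt + (1 - eprime_opt) * (ep0 - qm) / (1 - qm))
  # map back onto the original energy scale (monotone in the input)
  lo + (1 - g) * (hi - lo)
}

#' Normalize a raw landscape to the [0, 1] scale
#'
#' Scores are referenced to the consensus sequence:
#' `eprime = (eps_min - eps) / (eps_min - eps_max)` where `eps_max` is
#' the (numerically lowest) consensus score and `eps_min` the worst
#' score, so the consensus maps to 1 and the worst site to 0. Ties for
#' the consensus are broken by lexicographic order of the 8-mer.
#'
#' @param raw A `raw_landscape`.
#' @return An object of class `normalized_landscape` with fields
#'   `tf_id`, `eprime` (length 65,536) and `consensus` (index of the
#'   consensus 8-mer).
#' @export
normalize <- function(raw) {
  if (!inherits(raw, "raw_landscape")) stop("raw must be a raw_landscape")
  eps <- raw$epsilon
  lo <- min(eps)
  hi <- max(eps)
  if (hi <= lo) stop("degenerate landscape: all scores are equal")
  structure(
    list(tf_id = raw$tf_id,
         eprime = (hi - eps) / (hi - lo),
         consensus = which.min(eps)),
    class = "normalized_landscape"
  )
}

#' Slope parameter linked to the specificity gap
#'
#' The exponential slope lambda and the cutoff gamma are linked through
#' the binder threshold: kappa at `eprime = eprime_opt` must equal
#' gamma, giving `lambda = log(gamma) / (eprime_opt - 1)`.
#'
#' @param gamma Specificity gap in (0, 1).
#' @param eprime_opt Normalized-score threshold in (0, 1).
#' @return Positive scalar lambda.
#' @export
lambda_from_gamma <- function(gamma, eprime_opt = EPRIME_OPT) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1) {
    stop("gamma must lie in (0, 1)")
  }
  if (eprime_opt <= 0 || eprime_opt >= 1) stop("eprime_opt must lie in (0, 1)")
  log(gamma) / (eprime_opt - 1)
}

#' Specificity table of a transcription factor
#'
#' Applies the exponential specificity transform with cutoff:
#' `kappa = exp(lambda * (eprime - 1))` for `eprime >= eprime_opt`,
#' zero below. The consensus has kappa = 1; the weakest binder sits at
#' kappa = gamma; the jump from gamma to 0 is the specificity gap.
#'
#' @param norm A `normalized_landscape`.
#' @param gamma Specificity gap in (0, 1).
#' @param eprime_opt Binder threshold.
#' @return Object of class `specificity_table`: fields `tf_id`, `gamma`,
#'   `lambda`, `eprime_opt`, `kappa` (dense numeric of length 65,536,
#'   zero for non-binders), `binders` (integer indices) and
#'   `binder_count`.
#' @export
specificity <- function(norm, gamma, eprime_opt = EPRIME_OPT) {
  if (!inherits(norm, "normalized_landscape")) {
    stop("norm must be a normalized_landscape")
  }
  lambda <- lambda_from_gamma(gamma, eprime_opt)
  ep <- norm$eprime
  binders <- which(ep >= eprime_opt)
  kappa <- numeric(N_KMERS)
  kappa[binders] <- exp(lambda * (ep[binders] - 1))
  structure(
    list(tf_id = norm$tf_id, gamma = gamma, lambda = lambda,
         eprime_opt = eprime_opt, kappa = kappa, binders = binders,
         binder_count = length(binders)),
    class = "specificity_table"
  )
}

#' Build a specificity table directly from a sparse binder list
#'
#' Convenience constructor for toy landscapes in examples and tests: all
#' 8-mers absent from `kappa` get specificity zero.
#'
#' @param kappa Named numeric vector; names are binder 8-mers, values
#'   their specificities in (0, 1].
#' @param tf_id,gamma,eprime_opt Metadata carried by the table.
#' @return A `specificity_table`.
#' @export
specificity_from_binders <- function(kappa, tf_id = "TF1", gamma = 0.05,
                                     eprime_opt = EPRIME_OPT) {
  if (length(kappa) && is.null(names(kappa))) {
    stop("kappa must be named by 8-mer")
  }
  kappa <- stats::setNames(as.numeric(kappa),
                           if (length(kappa)) names(kappa) else character(0))
  idx <- encode_kmers(names(kappa))
  if (anyDuplicated(idx)) stop("duplicate 8-mers in kappa")
  dense <- numeric(N_KMERS)
  dense[idx] <- as.numeric(kappa)
  structure(
    list(tf_id = tf_id, gamma = gamma,
         lambda = lambda_from_gamma(gamma, eprime_opt),
         eprime_opt = eprime_opt, kappa = dense, binders = sort(idx),
         binder_count = length(idx)),
    class = "specificity_table"
  )
}

#' Fraction of single point mutants of a site that remain binders
#'
#' TFBS conservation of a binding site: the fraction of its 24
#' single-point mutants that are still binders (kappa > 0) for the same
#' factor.
#'
#' @param site An 8-mer that is a binder in `table`.
#' @param table A `specificity_table`.
#' @return A value in [0, 1].
#' @export
tfbs_conservation <- function(site, table) {
  idx <- encode_kmers(site)
  if (table$kappa[idx] <= 0) {
    stop("site '", site, "' is not a binder for ", table$tf_id)
  }
  nbrs <- mutant_index_matrix()[idx, ]
  mean(table$kappa[nbrs] > 0)
}

# Internal vectorized form: conservation for every binder index of a
# table at once.
conservation_by_index <- function(idx, table) {
  nb <- mutant_index_matrix()
  bound <- table$kappa > 0
  vapply(idx, function(i) mean(bound[nb[i, ]]), numeric(1))
}

#' Generate a panel of synthetic transcription-factor landscapes
#'
#' One independently seeded landscape per factor. By default the panel
#' has 10 factors whose binder counts are drawn log-uniformly from
#' [60, 900], the empirically calibrated per-factor range.
#'
#' @param n_tf Number of factors.
#' @param gamma Specificity gap applied to every factor.
#' @param eprime_opt Binder threshold.
#' @param n_binders Optional integer vector of per-factor binder counts;
#'   drawn log-uniformly from `binder_range` when NULL.
#' @param binder_range Range for the log-uniform binder-count draw.
#' @param additive_sd,epistasis_weight Generator shape parameters.
#' @param seed Master seed; per-factor seeds are derived from it.
#' @return Object of class `landscape_panel`: list with `tables` (list of
#'   `specificity_table`), `raw`, `norm` (matching lists), `gamma`,
#'   `eprime_opt`, `seed`.
#' @export
generate_landscape_panel <- function(n_tf = 10L, gamma = 0.05,
                                     eprime_opt = EPRIME_OPT,
                                     n_binders = NULL,
                                     binder_range = c(60L, 900L),
                                     additive_sd = 1,
                                     epistasis_weight = 0.2,
                                     seed = NULL) {
  n_tf <- as.integer(n_tf)
  if (n_tf < 1L) stop("n_tf must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_binders)) {
    lo <- log(binder_range[1])
    hi <- log(binder_range[2])
    n_binders <- as.integer(round(exp(stats::runif(n_tf, lo, hi))))
  } else if (length(n_binders) == 1L) {
    n_binders <- rep(as.integer(n_binders), n_tf)
  }
  if (length(n_binders) != n_tf) {
    stop("n_binders must have length 1 or n_tf")
  }
  tf_seeds <- sample.int(.Machine$integer.max, n_tf)

  raw <- vector("list", n_tf)
  norm <- vector("list", n_tf)
  tables <- vector("list", n_tf)
  for (j in seq_len(n_tf)) {
    p <- landscape_params(n_binders = n_binders[j],
                          additive_sd = additive_sd,
                          epistasis_weight = epistasis_weight,
                          eprime_opt = eprime_opt,
                          seed = tf_seeds[j],
                          tf_id = paste0("TF", j))
    raw[[j]] <- generate_raw_landscape(p)
    norm[[j]] <- normalize(raw[[j]])
    tables[[j]] <- specificity(norm[[j]], gamma, eprime_opt)
  }
  structure(
    list(tables = tables, raw = raw, norm = norm, gamma = gamma,
         eprime_opt = eprime_opt, n_binders = n_binders, seed = seed,
         tf_seeds = tf_seeds),
    class = "landscape_panel"
  )
}

#' Assemble a panel from pre-built specificity tables
#'
#' @param tables List of `specificity_table` objects.
#' @return A `landscape_panel` (without raw/normalized components).
#' @export
panel_from_tables <- function(tables) {
  if (!length(tables) || !all(vapply(tables, inherits, logical(1),
                                     "specificity_table"))) {
    stop("tables must be a non-empty list of specificity_table objects")
  }
  structure(
    list(tables = tables, raw = NULL, norm = NULL,
         gamma = tables[[1]]$gamma, eprime_opt = tables[[1]]$eprime_opt,
         n_binders = vapply(tables, `[[`, integer(1), "binder_count"),
         seed = NULL),
    class = "landscape_panel"
  )
}

# Dense 65536 x n_tf kappa matrix used by the scanner.
kappa_matrix <- function(panel) {
  km <- attr(panel, "kappa_matrix")
  if (is.null(km)) {
    km <- vapply(panel$tables, `[[`, numeric(N_KMERS), "kappa")
  }
  km
}

# Panel with the kappa matrix cached on it (call once before hot loops).
prime_panel <- function(panel) {
  if (is.null(attr(panel, "kappa_matrix"))) {
    attr(panel, "kappa_matrix") <- kappa_matrix(panel)
  }
  if (is.null(attr(panel, "any_binder"))) {
    attr(panel, "any_binder") <-
      rowSums(attr(panel, "kappa_matrix") > 0) > 0
  }
  panel
}

#' @export
print.landscape_panel <- function(x, ...) {
  cat("<landscape_panel> ", length(x$tables), " TFs, gamma = ", x$gamma,
      ", eprime_opt = ", x$eprime_opt, "\n", sep = "")
  cat("  binder counts:", paste(x$n_binders, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.specificity_table <- function(x, ...) {
  cat("<specificity_table> ", x$tf_id, ": ", x$binder_count,
      " binders, gamma = ", x$gamma, ", lambda = ",
      format(x$lambda, digits = 6), "\n", sep = "")
  invisible(x)
}
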