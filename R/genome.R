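# Genotypes are explicit upstream regulatory regions (URRs): one DNA
# string of length L per gene, plus per-gene activator/repressor signs
# and a fixed binary initial expression state. Scanning the L-7
# overlapping 8-mer windows of every URR against the specificity tables
# yields site annotations and the interaction matrix w, with
# w[i, j] = sum of kappa over factor j's sites in gene i's URR.
#
# Coordinates are 0-based; a site at offset o occupies the half-open
# window [o, o + 8). Only the forward strand is scanned.

#' Random URR sequence
#'
#' Uniform i.i.d. bases over A, C, G, T.
#'
#' @param L Sequence length in bp (>= 8).
#' @return A DNA string of length `L`.
#' @export
random_urr <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < KMER_LEN) stop("L must be >= ", KMER_LEN)
  codes_to_dna(sample.int(4L, L, replace = TRUE) - 1L)
}

#' Construct a genotype
#'
#' @param urrs Character vector of n URR DNA strings, all the same
#'   length L.
#' @param tf_signs Integer vector in {-1, +1}: activator/repressor role
#'   of each gene product, fixed for a simulation.
#' @param initial_state Numeric vector in {0, 1}: initial expression,
#'   fixed for a simulation.
#' @return Object of class `genotype` with fields `urrs` (list of
#'   integer base codes), `tf_signs`, `initial_state`, `n`, `L`.
#' @export
new_genotype <- function(urrs, tf_signs, initial_state) {
  if (is.character(urrs)) {
    lens <- nchar(urrs)
    if (length(unique(lens)) != 1L) stop("all URRs must have equal length")
    codes <- lapply(urrs, dna_to_codes)
  } else if (is.list(urrs)) {
    codes <- lapply(urrs, as.integer)
    lens <- lengths(codes)
    if (length(unique(lens)) != 1L) stop("all URRs must have equal length")
  } else {
    stop("urrs must be a character vector or list of code vectors")
  }
  n <- length(codes)
  L <- lens[1]
  if (L < KMER_LEN) stop("URR length must be >= ", KMER_LEN)
  tf_signs <- as.integer(tf_signs)
  if (length(tf_signs) != n || !all(tf_signs %in% c(-1L, 1L))) {
    stop("tf_signs must be a length-n vector over {-1, +1}")
  }
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != n || !all(initial_state %in% c(0, 1))) {
    stop("initial_state must be a length-n vector over {0, 1}")
  }
  structure(
    list(urrs = codes, tf_signs = tf_signs, initial_state = initial_state,
         n = n, L = as.integer(L)),
    class = "genotype"
  )
}

#' Draw a random genotype
#'
#' Random URRs, uniform activator/repressor signs, uniform binary
#' initial state.
#'
#' @param n Number of genes.
#' @param L URR length in bp.
#' @return A `genotype`.
#' @export
random_genotype <- function(n, L) {
  urrs <- lapply(seq_len(n), function(i) sample.int(4L, L, replace = TRUE) - 1L)
  new_genotype(urrs,
               tf_signs = sample(c(-1L, 1L), n, replace = TRUE),
               initial_state = sample(c(0, 1), n, replace = TRUE))
}

#' URR sequences of a genotype as strings
#'
#' @param genotype A `genotype`.
#' @return Character vector of DNA strings.
#' @export
urr_strings <- function(genotype) {
  vapply(genotype$urrs, codes_to_dna, character(1))
}

# Scan one coded URR against the dense kappa matrix.
# Returns list(w_row, offset (0-based int), tf (int), kappa (numeric)).
scan_codes <- function(codes, km) {
  idx <- window_indices(codes)
  sub <- km[idx, , drop = FALSE]
  hit <- which(sub > 0)
  nw <- length(idx)
  offset <- as.integer((hit - 1L) %% nw)
  tf <- as.integer((hit - 1L) %/% nw) + 1L
  kappa <- sub[hit]
  w_row <- numeric(ncol(km))
  if (length(hit)) {
    sums <- rowsum(kappa, tf)
    w_row[as.integer(rownames(sums))] <- sums[, 1]
  }
  list(w_row = w_row, offset = offset, tf = tf, kappa = kappa)
}

#' Annotate the binding sites of one URR
#'
#' Examines all L-7 forward-strand 8-mer windows against every factor's
#' specificity table; overlapping and nested sites are all reported, and
#' a window bound by several factors yields one annotation per factor.
#'
#' @param urr A DNA string (length >= 8).
#' @param panel A `landscape_panel` (or list of `specificity_table`).
#' @return A data.frame with columns `offset` (0-based window start),
#'   `tf` (factor index) and `kappa`.
#' @export
scan_urr <- function(urr, panel) {
  panel <- as_panel(panel)
  hits <- scan_codes(dna_to_codes(urr), kappa_matrix(panel))
  ord <- order(hits$offset, hits$tf)
  data.frame(offset = hits$offset[ord], tf = hits$tf[ord],
             kappa = hits$kappa[ord])
}

as_panel <- function(panel) {
  if (inherits(panel, "landscape_panel")) return(panel)
  if (is.list(panel) && all(vapply(panel, inherits, logical(1),
                                   "specificity_table"))) {
    return(panel_from_tables(panel))
  }
  stop("expected a landscape_panel or a list of specificity tables")
}

#' Build the regulatory network of a genotype
#'
#' @param genotype A `genotype` with n genes.
#' @param panel A `landscape_panel` with one table per gene product.
#' @return Object of class `regulatory_network`: `w` (n x n matrix,
#'   `w[i, j]` = summed kappa of factor j's sites in gene i's URR) and
#'   `sites` (data.frame gene/tf/offset/kappa).
#' @export
build_network <- function(genotype, panel) {
  panel <- as_panel(panel)
  n_tf <- length(panel$tables)
  if (n_tf != genotype$n) {
    stop("panel has ", n_tf, " tables but genotype has ", genotype$n,
         " genes")
  }
  km <- kappa_matrix(panel)
  scans <- lapply(genotype$urrs, scan_codes, km = km)
  network_from_scans(scans, genotype$n)
}

network_from_scans <- function(scans, n) {
  w <- do.call(rbind, lapply(scans, `[[`, "w_row"))
  sites <- data.frame(
    gene = rep(seq_len(n), vapply(scans, function(s) length(s$offset),
                                  integer(1))),
    tf = unlist(lapply(scans, `[[`, "tf"), use.names = FALSE),
    offset = unlist(lapply(scans, `[[`, "offset"), use.names = FALSE),
    kappa = unlist(lapply(scans, `[[`, "kappa"), use.names = FALSE)
  )
  if (nrow(sites) == 0) {
    sites <- data.frame(gene = integer(), tf = integer(),
                        offset = integer(), kappa = numeric())
  }
  structure(list(w = w, sites = sites), class = "regulatory_network")
}

#' Network connectivity
#'
#' Fraction of nonzero entries of the interaction matrix.
#'
#' @param network A `regulatory_network` (or plain matrix).
#' @return Value in [0, 1].
#' @export
connectivity <- function(network) {
  w <- if (inherits(network, "regulatory_network")) network$w else network
  mean(w != 0)
}

#' Apply random point mutations to a genotype
#'
#' Each base mutates independently with probability `rate_per_bp`
#' (default 1 mutation per 100 bp of genome in expectation); a mutating
#' base is replaced by one of the three alternatives uniformly.
#'
#' @param genotype A `genotype`.
#' @param rate_per_bp Per-base mutation probability in [0, 1].
#' @return List with `genotype` (the mutated copy) and `mutations`, a
#'   data.frame with columns `gene`, `position` (0-based), `old_base`,
#'   `new_base`.
#' @export
point_mutate <- function(genotype, rate_per_bp = 0.01) {
  if (rate_per_bp < 0 || rate_per_bp > 1) {
    stop("rate_per_bp must lie in [0, 1]")
  }
  n <- genotype$n
  L <- genotype$L
  total <- n * L
  hits <- which(stats::runif(total) < rate_per_bp)
  if (!length(hits)) {
    return(list(genotype = genotype,
                mutations = data.frame(gene = integer(), position = integer(),
                                       old_base = character(),
                                       new_base = character())))
  }
  gene <- ((hits - 1L) %/% L) + 1L
  pos <- (hits - 1L) %% L # 0-based
  out <- genotype
  old <- integer(length(hits))
  newb <- integer(length(hits))
  for (k in seq_along(hits)) {
    g <- gene[k]
    p <- pos[k] + 1L
    old[k] <- out$urrs[[g]][p]
    newb[k] <- (old[k] + sample.int(3L, 1L)) %% 4L
    out$urrs[[g]][p] <- newb[k]
  }
  list(genotype = out,
       mutations = data.frame(gene = gene, position = pos,
                              old_base = BASES[old + 1L],
                              new_base = BASES[newb + 1L]))
}

#' Sexual reproduction by whole-URR reassortment
#'
#' For each gene independently, the offspring inherits that gene's URR
#' from one of the two parents with equal probability; there is no
#' recombination within a URR. Signs and initial state are inherited
#' unchanged.
#'
#' @param parent_a,parent_b Compatible `genotype`s (same n, L, signs and
#'   initial state).
#' @return The offspring `genotype`.
#' @export
recombine <- function(parent_a, parent_b) {
  if (parent_a$n != parent_b$n || parent_a$L != parent_b$L ||
      !identical(parent_a$tf_signs, parent_b$tf_signs) ||
      !identical(parent_a$initial_state, parent_b$initial_state)) {
    stop("incompatible parents: n, L, tf_signs and initial_state must match")
  }
  pick <- stats::runif(parent_a$n) < 0.5
  out <- parent_a
  out$urrs[!pick] <- parent_b$urrs[!pick]
  out
}

#' Fraction of the genome not covered by any binding-site footprint
#'
#' A site at offset o covers the 8 positions [o, o + 8); footprints of
#' all factors are unioned per gene.
#'
#' @param genotype The `genotype` the network was built from.
#' @param network Its `regulatory_network`.
#' @return Value in [0, 1].
#' @export
tfbs_free_fraction <- function(genotype, network) {
  L <- genotype$L
  covered <- 0L
  for (i in seq_len(genotype$n)) {
    off <- network$sites$offset[network$sites$gene == i]
    if (length(off)) {
      mask <- logical(L)
      for (o in unique(off)) mask[(o + 1L):(o + KMER_LEN)] <- TRUE
      covered <- covered + sum(mask)
    }
  }
  1 - covered / (genotype$n * L)
}

#' Number of redundant binding sites in a network
#'
#' For each realized (gene, factor) input, sites beyond the first are
#' redundant; their total count is returned.
#'
#' @param network A `regulatory_network`.
#' @return Non-negative integer.
#' @export
redundancy_count <- function(network) {
  s <- network$sites
  if (!nrow(s)) return(0L)
  nrow(s) - length(unique(s$gene * 1000000L + s$tf))
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> ", x$n, " genes, L = ", x$L, " bp\n", sep = "")
  cat("  signs:", paste(ifelse(x$tf_signs > 0, "+", "-"), collapse = ""),
      " initial:", paste(x$initial_state, collapse = ""), "\n")
  invisible(x)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", nrow(x$w), "x", ncol(x$w),
      ", connectivity = ", format(connectivity(x), digits = 3),
      ", ", nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}
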