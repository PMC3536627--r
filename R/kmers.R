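# 8-mer indexing machinery shared by all modules.
#
# Every 8-mer over {A,C,G,T} is identified with an integer index in
# 1..65536 via big-endian base-4 encoding (A=0, C=1, G=2, T=3), so that
# numeric order of indices equals lexicographic order of sequences.

KMER_LEN <- 8L
N_KMERS <- 65536L
BASES <- c("A", "C", "G", "T")

# lazily populated cache of large shared tables (digit matrix, neighbour
# matrix, kmer strings)
.cisnet_cache <- new.env(parent = emptyenv())

#' @keywords internal
kmer_digit_matrix <- function() {
  m <- .cisnet_cache$digits
  if (is.null(m)) {
    i <- 0:(N_KMERS - 1L)
    m <- matrix(0L, nrow = N_KMERS, ncol = KMER_LEN)
    for (p in seq_len(KMER_LEN)) {
      m[, p] <- as.integer((i %/% 4L^(KMER_LEN - p)) %% 4L)
    }
    .cisnet_cache$digits <- m
  }
  m
}

#' All 65,536 8-mers in lexicographic (= index) order
#'
#' @return Character vector of length 65,536.
#' @export
all_kmers <- function() {
  k <- .cisnet_cache$kmers
  if (is.null(k)) {
    m <- kmer_digit_matrix()
    k <- do.call(paste0, lapply(seq_len(KMER_LEN), function(p) BASES[m[, p] + 1L]))
    .cisnet_cache$kmers <- k
  }
  k
}

#' Convert 8-mer strings to integer indices
#'
#' @param kmers Character vector of 8-mers over ACGT.
#' @return Integer vector of indices in 1..65536.
#' @export
encode_kmers <- function(kmers) {
  if (!is.character(kmers)) stop("kmers must be a character vector")
  if (any(nchar(kmers) != KMER_LEN)) {
    stop("all k-mers must have length ", KMER_LEN)
  }
  codes <- dna_to_codes(paste0(kmers, collapse = ""))
  m <- matrix(codes, nrow = KMER_LEN)
  pow <- 4L^(KMER_LEN - seq_len(KMER_LEN))
  as.integer(colSums(m * pow) + 1L)
}

#' Convert integer indices back to 8-mer strings
#'
#' @param idx Integer vector of indices in 1..65536.
#' @return Character vector of 8-mers.
#' @export
decode_kmers <- function(idx) {
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > N_KMERS)) {
    stop("indices must lie in 1..", N_KMERS)
  }
  all_kmers()[idx]
}

# DNA string -> integer codes 0..3; errors on non-ACGT characters
dna_to_codes <- function(seq) {
  raw <- utf8ToInt(seq)
  codes <- rep(NA_integer_, length(raw))
  codes[raw == 65L] <- 0L # A
  codes[raw == 67L] <- 1L # C
  codes[raw == 71L] <- 2L # G
  codes[raw == 84L] <- 3L # T
  if (anyNA(codes)) {
    bad <- intToUtf8(raw[which(is.na(codes))[1]])
    stop("invalid DNA character: '", bad, "' (only A, C, G, T allowed)")
  }
  codes
}

codes_to_dna <- function(codes) {
  paste0(BASES[codes + 1L], collapse = "")
}

# Window indices of all L-7 overlapping 8-mers of a coded sequence.
# codes: integer vector (0..3) of length L >= 8. Returns integer vector
# of length L-7 with values in 1..65536.
window_indices <- function(codes) {
  L <- length(codes)
  nw <- L - KMER_LEN + 1L
  if (nw < 1L) stop("sequence shorter than ", KMER_LEN)
  idx <- numeric(nw)
  for (k in seq_len(KMER_LEN)) {
    idx <- idx + codes[k:(k + nw - 1L)] * 4^(KMER_LEN - k)
  }
  as.integer(idx + 1)
}

# 65536 x 24 integer matrix: row i lists the indices of all Hamming-
# distance-1 neighbours of 8-mer i. Column order: position-major,
# substitution offset minor.
mutant_index_matrix <- function() {
  nb <- .cisnet_cache$neighbours
  if (is.null(nb)) {
    m <- kmer_digit_matrix()
    idx <- seq_len(N_KMERS)
    nb <- matrix(0L, nrow = N_KMERS, ncol = 3L * KMER_LEN)
    col <- 0L
    for (p in seq_len(KMER_LEN)) {
      pow <- 4L^(KMER_LEN - p)
      for (d in 1:3) {
        col <- col + 1L
        newdig <- (m[, p] + d) %% 4L
        nb[, col] <- idx + (newdig - m[, p]) * pow
      }
    }
    .cisnet_cache$neighbours <- nb
  }
  nb
}

#' All single point mutants of an 8-mer
#'
#' Returns the 8 x 3 = 24 sequences at Hamming distance exactly 1 from
#' `site`.
#'
#' @param site A single 8-mer string over ACGT.
#' @return Character vector of 24 distinct 8-mers, excluding `site`.
#' @export
single_point_mutants <- function(site) {
  if (!is.character(site) || length(site) != 1L) {
    stop("site must be a single string")
  }
  idx <- encode_kmers(site)
  decode_kmers(mutant_index_matrix()[idx, ])
}
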