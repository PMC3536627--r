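# Plain-text interchange: landscapes as TSV (one file per factor),
# genotypes as FASTA + JSON sidecar, trajectories as JSONL, and run
# manifests as JSON.

LANDSCAPE_COLUMNS <- c("kmer", "epsilon", "epsilon_prime", "kappa")

#' Bundle the three score maps of one factor
#'
#' @param raw A `raw_landscape`.
#' @param norm Its `normalized_landscape`.
#' @param table Its `specificity_table`.
#' @return Object of class `tf_landscape`.
#' @export
tf_landscape <- function(raw, norm, table) {
  structure(list(tf_id = table$tf_id, raw = raw, norm = norm,
                 table = table),
            class = "tf_landscape")
}

#' Extract one factor's landscape bundle from a panel
#'
#' @param panel A generated `landscape_panel`.
#' @param j Factor index.
#' @return A `tf_landscape`.
#' @export
panel_landscape <- function(panel, j) {
  if (is.null(panel$raw)) {
    stop("panel carries no raw landscapes (built from tables only)")
  }
  tf_landscape(panel$raw[[j]], panel$norm[[j]], panel$tables[[j]])
}

#' Write a landscape to a tab-separated table
#'
#' Columns `kmer`, `epsilon`, `epsilon_prime`, `kappa`; 65,536 rows in
#' lexicographic k-mer order; scores at full double precision.
#'
#' @param landscape A `tf_landscape` (see [panel_landscape()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  if (!inherits(landscape, "tf_landscape")) {
    stop("landscape must be a tf_landscape")
  }
  dt <- data.table::data.table(
    kmer = all_kmers(),
    epsilon = landscape$raw$epsilon,
    epsilon_prime = landscape$norm$eprime,
    kappa = landscape$table$kappa
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' Validates the column set, the 65,536-row count and k-mer uniqueness.
#' The specificity gap is recovered as the smallest positive kappa and
#' the binder threshold as the smallest epsilon_prime among binders.
#'
#' @param path File path.
#' @param tf_id Identifier for the reconstructed landscape.
#' @return A `tf_landscape`.
#' @export
read_landscape <- function(path, tf_id = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "kmer"))
  missing <- setdiff(LANDSCAPE_COLUMNS, names(dt))
  if (length(missing)) {
    stop("landscape file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(dt) != N_KMERS) {
    stop("landscape file has ", nrow(dt), " rows; expected ", N_KMERS)
  }
  idx <- encode_kmers(dt$kmer)
  if (anyDuplicated(idx)) stop("duplicate k-mer rows in landscape file")
  ord <- order(idx)
  eps <- dt$epsilon[ord]
  ep <- dt$epsilon_prime[ord]
  kappa <- dt$kappa[ord]
  binders <- which(kappa > 0)
  if (!length(binders)) stop("landscape file contains no binders")
  gamma <- min(kappa[binders])
  eprime_opt <- min(ep[binders])
  raw <- structure(list(tf_id = tf_id, epsilon = eps, params = NULL),
                   class = "raw_landscape")
  norm <- structure(list(tf_id = tf_id, eprime = ep,
                         consensus = which.min(eps)),
                    class = "normalized_landscape")
  table <- structure(
    list(tf_id = tf_id, gamma = gamma,
         lambda = lambda_from_gamma(gamma, eprime_opt),
         eprime_opt = eprime_opt, kappa = kappa, binders = binders,
         binder_count = length(binders)),
    class = "specificity_table"
  )
  tf_landscape(raw, norm, table)
}

#' Export a genotype as FASTA plus a JSON sidecar
#'
#' One record per gene with IDs `gene1`, `gene2`, ...; signs, initial
#' state and L go to `<path>.json`.
#'
#' @param genotype A `genotype`.
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
write_genotype_fasta <- function(genotype, path) {
  seqs <- urr_strings(genotype)
  ids <- paste0("gene", seq_len(genotype$n))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(paste0(">", ids, "\n", seqs), path)
  }
  jsonlite::write_json(
    list(n = genotype$n, L = genotype$L,
         tf_signs = genotype$tf_signs,
         initial_state = genotype$initial_state),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a genotype written by [write_genotype_fasta()]
#'
#' @param path FASTA path (sidecar `<path>.json` must exist).
#' @return A `genotype`.
#' @export
read_genotype_fasta <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing genotype sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(x)
  } else {
    lines <- readLines(path)
    heads <- grepl("^>", lines)
    grp <- cumsum(heads)
    seqs <- vapply(split(lines[!heads], grp[!heads]), paste0,
                   character(1), collapse = "")
  }
  ord <- order(as.integer(sub("^gene", "", names(seqs))))
  new_genotype(unname(seqs[ord]), meta$tf_signs, meta$initial_state)
}

# Flatten a trajectory record into JSON-friendly scalars/vectors.
record_to_json <- function(rec) {
  out <- rec[c("generation", "connectivity", "redundancy", "phi_raw",
               "free_fraction", "replaced_fraction", "mean_fitness")]
  if (!is.null(rec$event_table)) {
    et <- rec$event_table
    out$robustness <- rec$robustness
    out$fraction_stable <- rec$fraction_stable
    out$event_f <- as.list(et$f)
    out$event_e <- as.list(et$e)
    out$event_counts <- as.list(et$counts)
  }
  out
}

#' Write trajectory records as JSON lines
#'
#' @param records List of trajectory records (from a `sim_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(record_to_json(rec), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read a trajectory JSONL file
#'
#' @param path File path.
#' @return List of records (plain lists).
#' @export
read_trajectory_jsonl <- function(path) {
  lapply(readLines(path), function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE)
  })
}

#' Write a run manifest
#'
#' Captures configuration, seeds, file digests and package version so a
#' run can be reproduced byte-for-byte under the same implementation.
#'
#' @param config A `sim_config` (or any list of settings).
#' @param path Output path.
#' @param files Optional character vector of produced files to digest.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, files = character(0),
                           extra = list()) {
  digests <- if (length(files)) {
    stats::setNames(as.list(tools::md5sum(files)), basename(files))
  } else {
    NULL
  }
  manifest <- c(
    list(package = "cisnet",
         version = as.character(utils::packageVersion("cisnet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config),
         file_digests = digests),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
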