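#' Dataset curation thresholds
#'
#' Defaults mirror the curation rules used for the protease-clan dataset:
#' at least 138 modeled residues (large enough to span both beta-barrel
#' domains), at most 10 missing residues, resolution at most 4.0 Angstrom
#' (structures with unknown resolution, e.g. NMR models, pass), and a 70%
#' pairwise sequence-identity cap for redundancy removal.
#'
#' @param min_length minimum number of modeled residues (inclusive).
#' @param max_missing maximum number of missing residues (inclusive).
#' @param max_resolution maximum resolution in Angstrom (inclusive).
#' @param max_identity identity fraction above which two sequences are
#'   considered redundant, in (0, 1].
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(min_length = 138L, max_missing = 10L,
                          max_resolution = 4.0, max_identity = 0.70) {
  stopifnot(min_length >= 1, max_missing >= 0, max_resolution > 0,
            max_identity > 0, max_identity <= 1)
  structure(list(min_length = as.integer(min_length),
                 max_missing = as.integer(max_missing),
                 max_resolution = max_resolution,
                 max_identity = max_identity),
            class = "FilterConfig")
}

#' Apply the dataset curation filters
#'
#' Keeps models with modeled length `>= min_length`, missing-residue count
#' `<= max_missing`, and resolution unknown or `<= max_resolution`.  The
#' report names every failed rule for every model so that manual curation
#' decisions (e.g. catalytic-site completeness, which no automatic rule
#' can judge) can be layered on top.
#'
#' @param models list of `StructureModel`.
#' @param cfg a [filter_config()].
#' @return list with `kept` (the surviving models) and `report` (data
#'   frame: `model_id`, `length`, `resolution`, `n_missing`, `kept`,
#'   `failed_rules` as comma-joined rule names).
#' @export
filter_dataset <- function(models, cfg = filter_config()) {
  stopifnot(inherits(cfg, "FilterConfig"))
  if (length(models) == 0L)
    return(list(kept = list(),
                report = data.frame(model_id = character(),
                                    length = integer(),
                                    resolution = numeric(),
                                    n_missing = integer(),
                                    kept = logical(),
                                    failed_rules = character(),
                                    stringsAsFactors = FALSE)))
  rows <- lapply(models, function(m) {
    failed <- character(0)
    if (length(m) < cfg$min_length) failed <- c(failed, "min_length")
    if (m$n_missing > cfg$max_missing) failed <- c(failed, "max_missing")
    if (!is.na(m$resolution) && m$resolution > cfg$max_resolution)
      failed <- c(failed, "max_resolution")
    data.frame(model_id = m$model_id, length = length(m),
               resolution = m$resolution, n_missing = m$n_missing,
               kept = length(failed) == 0L,
               failed_rules = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(kept = models[report$kept], report = report)
}

#' Smith-Waterman pairwise sequence identity
#'
#' Optimal local alignment under BLOSUM62 with affine gap penalties
#' (open 11, extend 1, configurable); identity is the number of identical
#' aligned positions divided by the number of aligned positions including
#' internal gaps.  A non-positive optimal score means no local similarity:
#' identity 0.  Symmetric by construction (arguments are ordered
#' canonically before aligning, so co-optimal alignments cannot make the
#' result direction-dependent).
#'
#' @param seq_a,seq_b non-empty amino-acid strings over the 20 standard
#'   letters plus `X`.
#' @param substitution_matrix name of the scoring matrix shipped with
#'   Biostrings.
#' @param gap_open,gap_extend positive gap penalties.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq_a) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq_b))
    stop("sequences must use the 20 standard letters plus X")
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  if (Biostrings::score(aln) <= 0) return(0)
  w <- Biostrings::nchar(aln)
  if (w == 0L) return(0)
  Biostrings::nmatch(aln) / w
}

#' Greedy identity clustering of structure models
#'
#' Redundancy removal in the spirit of CD-HIT's greedy incremental
#' algorithm: models are visited in order of decreasing sequence length
#' (ties broken by model id); each model joins the first existing cluster
#' whose representative shares identity above `max_identity` with it, and
#' otherwise founds a new cluster.  Cluster representatives (the longest
#' member seen first) are returned.
#'
#' @param models list of `StructureModel`.
#' @param max_identity identity threshold; members share identity strictly
#'   above this value with their representative.
#' @return list of representative `StructureModel`s, in founding order.
#' @export
identity_cluster <- function(models, max_identity = 0.70) {
  if (length(models) == 0L) return(list())
  seqs <- vapply(models, model_sequence, character(1))
  ids <- vapply(models, function(m) m$model_id, character(1))
  ord <- order(-nchar(seqs), ids)
  reps <- integer(0)
  for (k in ord) {
    joined <- FALSE
    for (r in reps) {
      idk <- pairwise_identity(seqs[k], seqs[r])
      # exact duplicates always join, even at max_identity = 1
      if (idk > max_identity || idk >= 1 - 1e-12) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, k)
  }
  models[reps]
}

#' Write a curation manifest as TSV
#'
#' @param report the `report` element of [filter_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(report, path) {
  df <- report
  df$resolution <- ifelse(is.na(df$resolution), "NA",
                          sprintf("%.2f", df$resolution))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
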