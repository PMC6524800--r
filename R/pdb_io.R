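#' Read one protein chain from a PDB file as a C-alpha structure model
#'
#' Parses standard fixed-column ATOM records (via [bio3d::read.pdb]) and
#' reduces one chain to its C-alpha trace.  For residues with alternate
#' locations the highest-occupancy conformer is kept (ties: the first
#' encountered).  HETATM records and waters are ignored.  The number of
#' missing residues is taken from SEQRES when present (declared length
#' minus modeled length) and otherwise from gaps in the author numbering.
#' The crystallographic resolution is read from the `REMARK   2` record
#' when present, else recorded as unknown (`NA`).
#'
#' Residues are ordered by author number, insertion codes sorting after
#' their base number ("20" < "20A" < "21").
#'
#' @param path path to a PDB file.
#' @param chain one-character chain identifier; `NULL` picks the first
#'   chain present.
#' @param model_id label for the model; default `<file stem>_<chain>`.
#' @param family_label,subfamily_label optional classification labels.
#' @return an object of class `StructureModel`: list with `model_id`,
#'   `residues` (data frame: `chain_id`, `res_seq`, `icode`, `aa`, `x`,
#'   `y`, `z`, `b_factor`), `resolution` (Angstrom or `NA`), `n_missing`,
#'   `family_label`, `subfamily_label`.
#' @export
read_structure <- function(path, chain = NULL, model_id = NULL,
                           family_label = "", subfamily_label = "") {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE, multi = FALSE,
                    verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA" & !(at$resid %in% "HOH"), ,
           drop = FALSE]
  if (nrow(at) == 0L)
    stop("no C-alpha atoms in file: ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' absent from file: ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc duplicates: keep highest occupancy, ties -> first encountered
  key <- paste(at$resno, at$insert, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(ix) ix[which.max(at$o[ix])]),
                 use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  at <- at[order(at$resno, at$insert), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% c(.AA20, "X")] <- "X"
  res <- data.frame(chain_id = at$chain, res_seq = at$resno,
                    icode = at$insert, aa = aa,
                    x = at$x, y = at$y, z = at$z,
                    b_factor = ifelse(is.na(at$b), NA_real_, at$b),
                    stringsAsFactors = FALSE)
  if (anyNA(res[, c("x", "y", "z")]))
    stop("non-finite C-alpha coordinates in file: ", path)
  n_missing <- .count_missing(pdb, chain, nrow(res), res$res_seq)
  if (is.null(model_id))
    model_id <- paste0(sub("\\.[^.]*$", "", basename(path)), "_", chain)
  new_structure_model(model_id, res, resolution = .parse_resolution(path),
                      n_missing = n_missing, family_label = family_label,
                      subfamily_label = subfamily_label)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.count_missing <- function(pdb, chain, n_modeled, res_seq) {
  sq <- pdb$seqres
  if (!is.null(sq) && length(sq) > 0 && any(names(sq) == chain)) {
    declared <- sum(names(sq) == chain)
    return(max(0L, declared - n_modeled))
  }
  u <- unique(res_seq)
  sum(pmax(diff(u) - 1L, 0L))
}

.parse_resolution <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[startsWith(ln, "REMARK   2 RESOLUTION")]
  if (length(ln) == 0L) return(NA_real_)
  tail_part <- sub(".*RESOLUTION\\.", "", ln[1])
  m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
  if (length(m) == 0L) return(NA_real_)
  as.numeric(m)
}

# Constructor with invariant checks.
new_structure_model <- function(model_id, residues, resolution = NA_real_,
                                n_missing = 0L, family_label = "",
                                subfamily_label = "") {
  stopifnot(nrow(residues) >= 1L)
  key <- paste(residues$res_seq, residues$icode)
  if (anyDuplicated(key))
    stop("duplicate (res_seq, icode) in model ", model_id)
  structure(
    list(model_id = model_id, residues = residues,
         resolution = resolution, n_missing = as.integer(n_missing),
         family_label = family_label, subfamily_label = subfamily_label),
    class = "StructureModel")
}

#' C-alpha coordinates of a structure model
#' @param model a `StructureModel`.
#' @return numeric N x 3 matrix (Angstrom).
#' @export
model_coords <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  as.matrix(model$residues[, c("x", "y", "z")])
}

#' One-letter amino-acid sequence of a structure model
#' @param model a `StructureModel`.
#' @return single character string.
#' @export
model_sequence <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  paste(model$residues$aa, collapse = "")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf(
    "StructureModel %s: %d residues, resolution %s, %d missing%s\n",
    x$model_id, nrow(x$residues),
    if (is.na(x$resolution)) "unknown" else sprintf("%.2f A", x$resolution),
    x$n_missing,
    if (nzchar(x$family_label)) paste0(" [", x$family_label,
      if (nzchar(x$subfamily_label)) paste0("/", x$subfamily_label), "]")
    else ""))
  invisible(x)
}

#' @export
length.StructureModel <- function(x) nrow(x$residues)

#' Trim a structure model to an author-numbering range
#'
#' Keeps residues with `first <= res_seq <= last` (author numbering;
#' insertion-coded residues belong to their base number), preserving order
#' and labels.  Used to cut multi-domain chains down to the domain of
#' interest before alignment.
#'
#' @param model a `StructureModel`.
#' @param first,last inclusive author-numbering bounds, `first <= last`.
#' @return trimmed `StructureModel`.
#' @export
trim_to_range <- function(model, first, last) {
  stopifnot(inherits(model, "StructureModel"), first <= last)
  keep <- model$residues$res_seq >= first & model$residues$res_seq <= last
  if (!any(keep))
    stop("trim range [", first, ", ", last, "] leaves no residues in ",
         model$model_id)
  out <- model
  out$residues <- model$residues[keep, , drop = FALSE]
  rownames(out$residues) <- NULL
  out
}

#' Write a C-alpha structure model as a PDB file
#'
#' Emits fixed-column `REMARK   2` (when the resolution is known), SEQRES
#' and ATOM records for the C-alpha trace, then TER/END.  Output is
#' deterministic, byte for byte, for identical models.
#'
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  res <- model$residues
  aa3 <- .aa123(res$aa)
  chain <- res$chain_id[1]
  lines <- character(0)
  if (!is.na(model$resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                              model$resolution))
  n <- nrow(res)
  for (k in seq_len(ceiling(n / 13))) {
    ix <- ((k - 1) * 13 + 1):min(k * 13, n)
    lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", k, chain, n,
                              paste(sprintf("%3s", aa3[ix]), collapse = " ")))
  }
  lines <- c(lines, sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), aa3, chain, res$res_seq,
    ifelse(nzchar(res$icode), res$icode, " "),
    res$x, res$y, res$z, 1.00,
    ifelse(is.na(res$b_factor), 0, res$b_factor)))
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", n + 1L, aa3[n],
                            chain, res$res_seq[n]), "END")
  writeLines(lines, path)
  invisible(path)
}

.AA123_MAP <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
                G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
                M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
                S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
                X = "UNK")
.aa123 <- function(aa) unname(.AA123_MAP[aa])
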