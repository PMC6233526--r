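
# -- Signature descriptors ----------------------------------------------------

.bond_char <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

.graph_parts <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  edges <- if (nrow(mol$bonds)) {
    as.matrix(mol$bonds[, c("from", "to")])
  } else {
    matrix(integer(), 0, 2)
  }
  list(labels = mol$labels, edges = edges,
       bonds = unname(.bond_char[mol$bonds$order]))
}

#' Signature generation settings
#'
#' @param heights non-negative integers: the subgraph heights to generate.
#'   The default `1:3` generates, for every atom, the canonical string of
#'   the subgraph of all atoms within distance 1, 2 and 3 of it.
#' @return an object of class `sig_config`.
#' @export
signature_config <- function(heights = 1:3) {
  heights <- sort(unique(as.integer(heights)))
  stopifnot(length(heights) >= 1, all(heights >= 0))
  structure(list(heights = heights), class = "sig_config")
}

#' Canonical signature of one atom at one height
#'
#' Returns the canonical string encoding of the induced subgraph of all
#' atoms within graph distance `height` of atom `root`, rooted at `root`.
#' The canonical form is the lexicographic minimum over all depth-first
#' serializations of that subgraph, so it is invariant under atom
#' renumbering and identical for symmetry-equivalent roots.
#'
#' @param mol a [molgraph()].
#' @param root atom index (1-based).
#' @param height non-negative integer.
#' @return a single character string (untagged; no height prefix).
#' @export
atom_signature <- function(mol, root, height) {
  stopifnot(inherits(mol, "molgraph"),
            root >= 1, root <= mol$n, height >= 0)
  g <- .graph_parts(mol)
  cpp_atom_signature(g$labels, g$edges, g$bonds,
                     as.integer(root), as.integer(height))
}

#' Signature count vector of a molecule
#'
#' Generates the canonical signature for every (atom, height) pair and
#' tabulates occurrence counts.  Signatures are tagged with their height
#' (`"h|signature"`), so identical subgraph strings arising at different
#' heights are distinct features.  For every configured height the counts
#' sum to the number of heavy atoms.
#'
#' @param mol a [molgraph()] or a SMILES string.
#' @param config a [signature_config()].
#' @return an object of class `sig_vector`: list with `counts` (named
#'   integer vector), `n_atoms`, `heights`.
#' @export
featurize <- function(mol, config = signature_config()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molgraph"), inherits(config, "sig_config"))
  g <- .graph_parts(mol)
  sigs <- cpp_all_signatures(g$labels, g$edges, g$bonds, config$heights)
  tags <- paste0(rep(config$heights, each = mol$n), "|", sigs)
  counts <- table(tags)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n_atoms = mol$n, heights = config$heights),
            class = "sig_vector")
}

# signatures for every (root, height) pair, untabulated; used by
# atom_contributions where the root atom of each occurrence matters
.atom_level_signatures <- function(mol, config) {
  g <- .graph_parts(mol)
  sigs <- cpp_all_signatures(g$labels, g$edges, g$bonds, config$heights)
  data.frame(atom = rep(seq_len(mol$n), times = length(config$heights)),
             height = rep(config$heights, each = mol$n),
             tag = paste0(rep(config$heights, each = mol$n), "|", sigs),
             stringsAsFactors = FALSE)
}

#' Featurize many molecules
#'
#' @param smiles character vector of SMILES.
#' @param config a [signature_config()].
#' @return list of `sig_vector`, one per input.
#' @export
featurize_all <- function(smiles, config = signature_config()) {
  # one batched canonicalization, then per-molecule graph + signatures
  canon <- canonical_smiles(smiles)
  bad <- which(is.na(canon))
  if (length(bad)) {
    stop(smiles_error(smiles[bad[1]], "rejected by chemistry backend"))
  }
  lapply(canon, function(s) featurize(parse_smiles(s, canonicalize = FALSE),
                                      config))
}

#' Build a frozen signature dictionary
#'
#' Assigns a stable column number to every signature occurring in any of
#' the given vectors.  Columns are 1-based and contiguous, in byte-wise
#' sorted order of the tagged signature strings, so the dictionary does not
#' depend on input order.
#'
#' @param vectors non-empty list of `sig_vector` objects.
#' @return an object of class `sig_dictionary`.
#' @export
build_dictionary <- function(vectors) {
  if (!length(vectors)) stop("cannot build a dictionary from zero vectors")
  sigs <- unique(unlist(lapply(vectors, function(v) names(v$counts)),
                        use.names = FALSE))
  sigs <- sort(sigs, method = "radix")
  structure(list(signatures = sigs, frozen = TRUE), class = "sig_dictionary")
}

#' @export
print.sig_dictionary <- function(x, ...) {
  cat(sprintf("<sig_dictionary> %d signatures (frozen)\n", length(x$signatures)))
  invisible(x)
}

#' Map a signature vector onto dictionary columns
#'
#' Signatures absent from the (frozen) dictionary are silently dropped; the
#' number dropped is available as attribute `n_dropped`.
#'
#' @param vector a `sig_vector`.
#' @param dict a `sig_dictionary`.
#' @return a sparse 1-row [Matrix::sparseMatrix()] of dimension
#'   `1 x length(dict$signatures)`.
#' @export
vectorize <- function(vector, dict) {
  stopifnot(inherits(vector, "sig_vector"), inherits(dict, "sig_dictionary"),
            isTRUE(dict$frozen))
  j <- match(names(vector$counts), dict$signatures)
  seen <- !is.na(j)
  out <- Matrix::sparseMatrix(
    i = rep(1L, sum(seen)), j = j[seen], x = as.numeric(vector$counts[seen]),
    dims = c(1L, length(dict$signatures)))
  attr(out, "n_dropped") <- sum(!seen)
  out
}

# rows = molecules, columns = dictionary entries
.sig_matrix <- function(vectors, dict) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_along(vectors)) {
    cnt <- vectors[[r]]$counts
    j <- match(names(cnt), dict$signatures)
    seen <- !is.na(j)
    ii <- c(ii, rep(r, sum(seen))); jj <- c(jj, j[seen])
    xx <- c(xx, as.numeric(cnt[seen]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(vectors), length(dict$signatures)))
}

# -- sparse dataset / dictionary files ---------------------------------------

#' Write and read a sparse dataset in LIBSVM text format
#'
#' One line per molecule: `label col:count ...` with 1-based, ascending
#' column indices, plus a sidecar dictionary file with one signature per
#' line (`column<TAB>height<TAB>signature`).
#'
#' @param vectors list of `sig_vector`.
#' @param labels vector of labels (written as-is).
#' @param dict a `sig_dictionary`.
#' @param path output path for the sparse data file.
#' @return `path`, invisibly.
#' @export
write_sparse_dataset <- function(vectors, labels, dict, path) {
  stopifnot(length(vectors) == length(labels))
  lines <- vapply(seq_along(vectors), function(r) {
    cnt <- vectors[[r]]$counts
    j <- match(names(cnt), dict$signatures)
    seen <- which(!is.na(j))
    seen <- seen[order(j[seen])]
    paste(c(as.character(labels[r]),
            sprintf("%d:%g", j[seen], cnt[seen])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparse_dataset
#' @export
read_sparse_dataset <- function(path, dict) {
  lines <- readLines(path)
  n <- length(lines); p <- length(dict$signatures)
  labels <- character(n)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_len(n)) {
    parts <- strsplit(lines[r], " ", fixed = TRUE)[[1]]
    labels[r] <- parts[1]
    if (length(parts) > 1) {
      kv <- strsplit(parts[-1], ":", fixed = TRUE)
      jj <- c(jj, vapply(kv, function(z) as.integer(z[1]), integer(1)))
      xx <- c(xx, vapply(kv, function(z) as.numeric(z[2]), numeric(1)))
      ii <- c(ii, rep(r, length(kv)))
    }
  }
  list(x = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p)),
       labels = labels)
}

#' @rdname write_sparse_dataset
#' @export
write_dictionary <- function(dict, path) {
  sp <- strsplit(dict$signatures, "|", fixed = TRUE)
  h <- vapply(sp, `[`, character(1), 1)
  s <- vapply(sp, function(z) paste(z[-1], collapse = "|"), character(1))
  writeLines(paste(seq_along(dict$signatures), h, s, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sparse_dataset
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  col <- vapply(parts, function(z) as.integer(z[1]), integer(1))
  sig <- vapply(parts, function(z) paste0(z[2], "|", z[3]), character(1))
  stopifnot(identical(col, seq_along(col)))
  structure(list(signatures = sig, frozen = TRUE), class = "sig_dictionary")
}
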