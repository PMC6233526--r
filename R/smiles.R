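
# -- SMILES input -------------------------------------------------------------
#
# All chemistry perception (validity, aromaticity, canonical form) is
# delegated to Open Babel via ChemmineOB.  Inputs are canonicalized first,
# so kekulized and aromatic spellings of the same molecule map to the same
# graph; the tokenizer below then only has to read Open Babel's canonical
# aromatic SMILES into an explicit heavy-atom graph.

.canon_cache <- new.env(parent = emptyenv())

.ob_convert <- function(smiles) {
  # one batch call; Open Babel stops a batch at the first bad molecule, so
  # anything missing from the output is retried one-by-one
  idx <- seq_along(smiles)
  src <- paste0(paste(smiles, idx), "\n", collapse = "")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = src),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, length(smiles))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      i <- suppressWarnings(as.integer(parts[2]))
      if (!is.na(i) && i >= 1 && i <= length(smiles)) res[i] <- parts[1]
    }
  }
  for (i in which(is.na(res))) {
    out1 <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = paste0(smiles[i], "\n")),
      error = function(e) "")
    can <- strsplit(out1, "[\t\n]")[[1]]
    if (length(can) >= 1 && nzchar(can[1])) res[i] <- can[1]
  }
  res
}

#' Canonical SMILES via the chemistry backend
#'
#' Converts SMILES strings to Open Babel canonical aromatic SMILES.
#' Unparseable strings yield `NA`.  Results are cached per input string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  res <- rep(NA_character_, length(smiles))
  known <- vapply(smiles, function(s) exists(s, envir = .canon_cache, inherits = FALSE), logical(1))
  res[known] <- vapply(smiles[known], function(s) get(s, envir = .canon_cache), character(1))
  todo <- which(!known)
  if (length(todo)) {
    uq <- unique(smiles[todo])
    conv <- .ob_convert(uq)
    names(conv) <- uq
    for (s in uq) assign(s, conv[[s]], envir = .canon_cache)
    res[todo] <- conv[smiles[todo]]
  }
  res
}

.aromatic_organic <- c("b", "c", "n", "o", "p", "s")
.organic_two <- c("Cl", "Br")
.organic_one <- c("B", "C", "N", "O", "P", "S", "F", "I")

.parse_bracket <- function(body, smiles) {
  # isotope
  body <- sub("^[0-9]+", "", body)
  aromatic <- FALSE
  if (grepl("^(se|as)", body)) {
    element <- paste0(toupper(substr(body, 1, 1)), substr(body, 2, 2))
    aromatic <- TRUE
    body <- substr(body, 3, nchar(body))
  } else if (grepl("^[A-Z][a-z]", body)) {
    element <- substr(body, 1, 2)
    body <- substr(body, 3, nchar(body))
  } else if (grepl("^[A-Z]", body)) {
    element <- substr(body, 1, 1)
    body <- substr(body, 2, nchar(body))
  } else if (grepl("^[a-z]", body)) {
    element <- toupper(substr(body, 1, 1))
    aromatic <- TRUE
    body <- substr(body, 2, nchar(body))
  } else {
    stop(smiles_error(smiles, "bad bracket atom"))
  }
  body <- gsub("@", "", body, fixed = TRUE)     # chirality ignored
  body <- sub("^H[0-9]*", "", body)             # explicit H count ignored
  charge <- 0L
  cm <- regmatches(body, regexpr("^([+-][0-9]+|[+]+|[-]+)", body))
  if (length(cm) && nzchar(cm)) {
    charge <- if (grepl("[0-9]", cm)) {
      as.integer(cm)
    } else {
      (if (substr(cm, 1, 1) == "+") 1L else -1L) * nchar(cm)
    }
  }
  list(element = element, aromatic = aromatic, charge = charge)
}

smiles_error <- function(smiles, reason) {
  structure(
    class = c("cpligand_smiles_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES '%s': %s", smiles, reason),
         call = NULL, smiles = smiles))
}

#' Construct a molecular graph directly
#'
#' Low-level constructor used by [parse_smiles()] and by tests that need
#' hand-built or permuted graphs.  Heavy atoms only; hydrogens are implicit.
#'
#' @param element character vector of element symbols.
#' @param aromatic logical vector, aromatic flag per atom.
#' @param charge integer vector of formal charges.
#' @param bonds data frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`).
#' @param smiles optional originating SMILES string.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(element, aromatic = rep(FALSE, length(element)),
                     charge = rep(0L, length(element)),
                     bonds = data.frame(from = integer(), to = integer(),
                                        order = character()),
                     smiles = NA_character_) {
  stopifnot(length(element) == length(aromatic),
            length(element) == length(charge),
            all(c("from", "to", "order") %in% names(bonds)))
  if (nrow(bonds)) {
    stopifnot(all(bonds$from >= 1), all(bonds$to <= length(element)),
              all(bonds$order %in% c("1", "2", "3", "ar")))
  }
  lab <- ifelse(aromatic, tolower(element), element)
  chg <- ifelse(charge == 0, "",
         ifelse(charge == 1, "+", ifelse(charge == -1, "-",
         sprintf("%+d", charge))))
  structure(
    list(n = length(element), element = element, aromatic = aromatic,
         charge = as.integer(charge),
         bonds = data.frame(from = as.integer(bonds$from),
                            to = as.integer(bonds$to),
                            order = as.character(bonds$order),
                            stringsAsFactors = FALSE),
         labels = paste0("[", lab, chg, "]"),
         smiles = smiles),
    class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds", x$n, nrow(x$bonds)))
  if (!is.na(x$smiles)) cat(" (", x$smiles, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' The string is first canonicalized (and aromaticity perceived) by the
#' Open Babel backend, then read into an explicit graph of heavy atoms and
#' bonds.  Stereochemistry, isotopes and explicit hydrogen counts are
#' ignored.  Multi-fragment SMILES (`.`) are allowed.
#'
#' @param smiles a single SMILES string.
#' @param canonicalize canonicalize via the backend first (default `TRUE`).
#'   With `FALSE` the literal string is tokenized as-is; use only for input
#'   that is already canonical aromatic SMILES.
#' @return a [molgraph()] object.
#' @export
parse_smiles <- function(smiles, canonicalize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) stop(smiles_error(smiles, "empty string"))
  raw <- smiles
  if (canonicalize) {
    smiles <- canonical_smiles(smiles)
    if (is.na(smiles)) stop(smiles_error(raw, "rejected by chemistry backend"))
  }

  element <- character(); aromatic <- logical(); charge <- integer()
  b_from <- integer(); b_to <- integer(); b_order <- character()
  prev <- NA_integer_
  pending <- NA_character_      # explicit bond symbol awaiting its atom
  stack <- integer()
  rings <- list()               # digit -> list(atom, bond)

  add_atom <- function(el, ar, ch) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    a <- length(element)
    if (!is.na(prev)) add_bond(prev, a, pending)
    pending <<- NA_character_
    prev <<- a
  }
  add_bond <- function(i, j, sym) {
    ord <- if (is.na(sym)) {
      if (aromatic[i] && aromatic[j]) "ar" else "1"
    } else {
      switch(sym, "-" = "1", "/" = "1", "\\" = "1",
             "=" = "2", "#" = "3", "$" = "3", ":" = "ar",
             stop(smiles_error(raw, paste0("bond symbol '", sym, "'"))))
    }
    b_from[length(b_from) + 1L] <<- i
    b_to[length(b_to) + 1L] <<- j
    b_order[length(b_order) + 1L] <<- ord
  }
  ring_mark <- function(key) {
    if (is.na(prev)) stop(smiles_error(raw, "ring bond before any atom"))
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
    } else {
      op <- rings[[key]]
      sym <- if (!is.na(op$bond)) op$bond else pending
      add_bond(op$atom, prev, sym)
      rings[[key]] <<- NULL
    }
    pending <<- NA_character_
  }

  i <- 1L; nc <- nchar(smiles)
  while (i <= nc) {
    ch <- substr(smiles, i, i)
    ch2 <- if (i < nc) substr(smiles, i, i + 1L) else ""
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, nc), fixed = TRUE)
      if (j < 0) stop(smiles_error(raw, "unclosed bracket"))
      at <- .parse_bracket(substr(smiles, i + 1L, i + j - 2L), raw)
      add_atom(at$element, at$aromatic, at$charge)
      i <- i + j
    } else if (ch2 %in% .organic_two) {
      add_atom(ch2, FALSE, 0L); i <- i + 2L
    } else if (ch %in% .organic_one) {
      add_atom(ch, FALSE, 0L); i <- i + 1L
    } else if (ch %in% .aromatic_organic) {
      add_atom(toupper(ch), TRUE, 0L); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop(smiles_error(raw, "unbalanced ')'"))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_mark(ch); i <- i + 1L
    } else if (ch == "%") {
      key <- substr(smiles, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", key)) stop(smiles_error(raw, "bad %nn ring bond"))
      ring_mark(key); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else {
      stop(smiles_error(raw, paste0("unexpected character '", ch, "'")))
    }
  }
  if (length(rings)) stop(smiles_error(raw, "unclosed ring bond"))
  if (!length(element)) stop(smiles_error(raw, "no atoms"))
  molgraph(element, aromatic, charge,
           data.frame(from = b_from, to = b_to, order = b_order,
                      stringsAsFactors = FALSE),
           smiles = smiles)
}
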