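# Low-level chemistry helpers on top of ChemmineR / ChemmineOB (OpenBabel).
#
# OpenBabel silently truncates syntactically broken SMILES instead of
# failing, so every entry point validates SMILES syntax first with a small
# tokenizer and refuses strings it cannot account for.

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# Tokenize one SMILES string. Returns a list with ok (logical), n_heavy
# (heavy-atom count, syntactic), and reason for rejection. The tokenizer
# checks balanced branches/brackets, paired ring-bond digits and legal
# atom symbols; it does not attempt valence checking (OpenBabel's job).
smiles_tokenize <- function(s) {
  fail <- function(msg) list(ok = FALSE, n_heavy = NA_integer_, reason = msg)
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    return(fail("empty or non-character SMILES"))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  depth <- 0L; n_heavy <- 0L; n_atoms <- 0L
  ring <- integer(0)
  last_was_atom <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(fail("unclosed bracket atom"))
      content <- substr(s, i + 1L, j - 1L)
      if (!grepl("^[0-9]*([A-IK-PR-Za-ik-pr-z][a-z]?|\\*|#[0-9]+)", content))
        return(fail(sprintf("illegal bracket atom '[%s]'", content)))
      elem <- sub("^[0-9]*", "", content)
      elem <- regmatches(elem, regexpr("^([A-Za-z][a-z]?|\\*|#[0-9]+)", elem))
      if (!identical(elem, "H") && !identical(elem, "h")) n_heavy <- n_heavy + 1L
      n_atoms <- n_atoms + 1L
      last_was_atom <- TRUE
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% ORGANIC_SUBSET) {
      n_heavy <- n_heavy + 1L; n_atoms <- n_atoms + 1L
      last_was_atom <- TRUE
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET || ch %in% AROMATIC_SUBSET || ch == "*") {
      n_heavy <- n_heavy + 1L; n_atoms <- n_atoms + 1L
      last_was_atom <- TRUE
      i <- i + 1L
    } else if (ch == "(") {
      if (!last_was_atom) return(fail("branch does not follow an atom"))
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(fail("unbalanced ')'"))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", ".")) {
      last_was_atom <- FALSE
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (!last_was_atom && !(i > 1L && chars[i - 1L] %in%
                                c(as.character(0:9), "-", "=", "#", ":", "/", "\\")))
        return(fail("ring-bond digit does not follow an atom"))
      ring <- c(ring, as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L)))
        return(fail("malformed %nn ring bond"))
      ring <- c(ring, as.integer(substr(s, i + 1L, i + 2L)))
      i <- i + 3L
    } else {
      return(fail(sprintf("illegal character '%s'", ch)))
    }
  }
  if (depth != 0L) return(fail("unbalanced '('"))
  tab <- table(ring)
  if (any(tab %% 2L != 0L)) return(fail("unpaired ring-bond digit"))
  if (n_atoms == 0L) return(fail("no atoms"))
  list(ok = TRUE, n_heavy = n_heavy, reason = NA_character_)
}

#' Validate SMILES strings
#'
#' Syntactic validation of SMILES: balanced branches and bracket atoms,
#' paired ring-bond digits, legal atom symbols. Used as a guard in front of
#' the OpenBabel readers, which truncate broken input silently.
#'
#' @param smiles character vector of SMILES strings.
#' @return invisibly `TRUE`; errors naming the first offending string.
#' @export
validate_smiles <- function(smiles) {
  for (s in smiles) {
    tk <- smiles_tokenize(s)
    if (!tk$ok)
      stop(sprintf("invalid SMILES '%s': %s", s, tk$reason), call. = FALSE)
  }
  invisible(TRUE)
}

#' Heavy-atom count of a SMILES string
#'
#' Counts non-hydrogen atoms syntactically (no 3D perception needed).
#'
#' @param smiles character vector.
#' @return integer vector of heavy-atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    tk <- smiles_tokenize(s)
    if (!tk$ok)
      stop(sprintf("invalid SMILES '%s': %s", s, tk$reason), call. = FALSE)
    tk$n_heavy
  }, integer(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form in one batched call.
#' Stereochemistry is preserved. Multi-fragment inputs stay multi-fragment;
#' use [desalt()] to strip counter-ions.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  validate_smiles(smiles)
  ids <- sprintf("q%08d", seq_along(smiles))
  inp <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  got <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                       character(1)))
  res <- can[match(ids, got)]
  if (anyNA(res)) {
    bad <- smiles[is.na(res)]
    stop(sprintf("OpenBabel could not canonicalize SMILES: %s",
                 paste(utils::head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  unname(res)
}

#' Split a SMILES string into fragments
#'
#' Splits on the top-level dot separator (dots never occur inside bracket
#' atoms).
#'
#' @param smiles a single SMILES string.
#' @return character vector of fragment SMILES.
#' @export
smiles_fragments <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  validate_smiles(smiles)
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

#' Parse SMILES into a ChemmineR SDFset
#'
#' @param smiles character vector of valid SMILES.
#' @param ids optional compound identifiers (defaults to the SMILES).
#' @return an [ChemmineR::SDFset] in input order.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  validate_smiles(smiles)
  if (is.null(ids)) ids <- smiles
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  x <- smiles
  names(x) <- ids
  ChemmineR::smiles2sdf(x)
}

# Internal: OpenBabel property table (MW, logP, HBD, formula, ...) for a
# SMILES vector, one row per molecule in input order. Handles single-atom
# fragments that ChemmineR's SDF reader rejects.
ob_props <- function(smiles) {
  validate_smiles(smiles)
  inp <- paste0(paste(smiles, sprintf("m%08d", seq_along(smiles)), sep = "\t"),
                collapse = "\n")
  rows <- ChemmineOB::forEachMol("SMILES", inp,
                                 function(m) ChemmineOB::prop_OB(m))
  df <- do.call(rbind, rows)
  if (nrow(df) != length(smiles))
    stop("OpenBabel failed to read every SMILES", call. = FALSE)
  df
}

#' Molecular weight from SMILES
#'
#' Average (formula-based) molecular weight as computed by OpenBabel.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector of molecular weights in daltons.
#' @export
mol_weight <- function(smiles) {
  unname(ob_props(smiles)$MW)
}

#' Alternative SMILES renderings of the same molecule
#'
#' Produces syntactically different SMILES strings for one molecule by
#' permuting its atom order and re-writing the structure. All renderings
#' canonicalize back to the same string; useful for testing atom-order
#' invariance of descriptors.
#'
#' @param smiles a single valid SMILES string.
#' @param n number of renderings.
#' @param seed integer seed for the atom permutations.
#' @return character vector of `n` SMILES strings.
#' @export
randomize_smiles <- function(smiles, n = 5L, seed = 1L) {
  stopifnot(length(smiles) == 1L, n >= 1L)
  sdf <- parse_smiles(smiles, ids = "m")[[1]]
  ab <- sdf@atomblock
  bb <- sdf@bondblock
  out <- character(n)
  set.seed(as.integer(seed))
  for (k in seq_len(n)) {
    perm <- sample(nrow(ab))
    inv <- order(perm)
    ab2 <- ab[perm, , drop = FALSE]
    bb2 <- bb
    bb2[, 1] <- inv[bb[, 1]]
    bb2[, 2] <- inv[bb[, 2]]
    sdf2 <- methods::new("SDF", header = sdf@header, atomblock = ab2,
                         bondblock = bb2, datablock = sdf@datablock)
    ss <- methods::new("SDFset", SDF = list(sdf2), ID = "m")
    out[k] <- as.character(ChemmineR::sdf2smiles(ss))[1]
  }
  out
}
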