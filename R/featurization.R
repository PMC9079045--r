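# Substructure fingerprints from SMARTS pattern sets, molecule
# standardization, Lipinski rule-of-five profiling, and an import adapter
# for externally computed descriptor matrices.

#' Construct a fingerprint matrix
#'
#' Container for compounds x features descriptor blocks: a numeric matrix
#' with compound ids as row names and feature names as column names, plus
#' the descriptor kind and provenance.
#'
#' @param values numeric matrix with dimnames; counts must be non-negative,
#'   presence values in \{0, 1\}.
#' @param kind `"count"` or `"presence"`.
#' @param provenance free-text source label (pattern-set name, `"external"`,
#'   `"synthetic"`).
#' @return object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(values, kind = c("count", "presence"),
                               provenance = "unknown") {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry compound ids (rownames) and feature names ",
         "(colnames)", call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate compound ids or feature names", call. = FALSE)
  if (any(is.na(values)))
    stop("fingerprint matrix contains missing values", call. = FALSE)
  if (any(values < 0))
    stop("fingerprint values must be non-negative", call. = FALSE)
  if (kind == "presence" && !all(values %in% c(0, 1)))
    stop("presence fingerprints must be binary", call. = FALSE)
  structure(list(compound_ids = rownames(values),
                 feature_names = colnames(values),
                 values = values, kind = kind,
                 provenance = provenance),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d compounds x %d features (%s, %s)\n",
              length(x$compound_ids), length(x$feature_names), x$kind,
              x$provenance))
  invisible(x)
}

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) x$values

#' Load a SMARTS pattern set
#'
#' Two-column text file (feature name, SMARTS; whitespace or tab
#' separated), `#` comments and blank lines allowed. Every pattern is
#' compiled against a probe molecule; a non-compiling SMARTS aborts with
#' the offending line number and pattern.
#'
#' @param path pattern file.
#' @return object of class `pattern_set`: data.frame with `name` and
#'   `smarts` in file order, attribute `source_name`.
#' @export
load_pattern_set <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  if (!length(keep)) stop("pattern file is empty", call. = FALSE)
  probe <- parse_smiles("CCO", ids = "probe")
  entries <- lapply(keep, function(i) {
    parts <- strsplit(trimws(raw[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: expected 'name SMARTS', got '%s'", i, raw[i]),
           call. = FALSE)
    ok <- tryCatch({
      suppressWarnings(ChemmineR::smartsSearchOB(probe, parts[2L],
                                                 uniqueMatches = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("line %d: SMARTS does not compile: %s (%s)",
                   i, parts[2L], parts[1L]), call. = FALSE)
    data.frame(name = parts[1L], smarts = parts[2L],
               stringsAsFactors = FALSE)
  })
  ps <- do.call(rbind, entries)
  if (anyDuplicated(ps$name))
    stop("duplicate feature names in pattern set: ",
         paste(unique(ps$name[duplicated(ps$name)]), collapse = ", "),
         call. = FALSE)
  structure(ps, class = c("pattern_set", "data.frame"),
            source_name = basename(path))
}

#' Bundled functional-group pattern set
#'
#' Loads the ~40-pattern SMARTS test set shipped with the package, covering
#' the descriptor classes most relevant to phenolic ER-alpha chemotypes.
#'
#' @return a `pattern_set`.
#' @export
default_pattern_set <- function() {
  load_pattern_set(system.file("extdata", "test_patterns.smarts",
                               package = "qsarflow", mustWork = TRUE))
}

# ---- molecular-graph helpers (kekulized SDF blocks) -----------------------

MOL_CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                     `5` = -1L, `6` = -2L, `7` = -3L)
STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                 F = 1, Cl = 1, Br = 1, I = 1)

sdf_elements <- function(sdf) sub("_.*$", "", rownames(sdf@atomblock))

sdf_charges <- function(sdf) {
  ab <- sdf@atomblock
  if ("C5" %in% colnames(ab)) {
    unname(MOL_CHARGE_CODE[as.character(ab[, "C5"])])
  } else rep(0L, nrow(ab))
}

# Implicit hydrogen count per atom from standard valences, adjusted for
# formal charge (N+ -> 4, O- -> 1, ...). Explicit hydrogens reduce the
# implicit count through the bond-order sum like any other neighbor.
sdf_implicit_h <- function(sdf) {
  el <- sdf_elements(sdf)
  ch <- sdf_charges(sdf)
  bb <- sdf@bondblock
  bsum <- rep(0, length(el))
  if (nrow(bb)) for (i in seq_len(nrow(bb))) {
    o <- bb[i, 3]
    bsum[bb[i, 1]] <- bsum[bb[i, 1]] + o
    bsum[bb[i, 2]] <- bsum[bb[i, 2]] + o
  }
  val <- STD_VALENCE[el]
  val[is.na(val)] <- 0
  pmax(0, round(val + ifelse(el %in% c("C", "B"), -abs(ch), ch) - bsum))
}

# Logical vector over bond rows: TRUE when the bond lies in a ring
# (removing it leaves its endpoints connected).
sdf_ring_bonds <- function(sdf) {
  bb <- sdf@bondblock
  n <- nrow(sdf@atomblock)
  if (!nrow(bb)) return(logical(0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(nrow(bb))) {
    a <- bb[i, 1]; b <- bb[i, 2]
    adj[[a]] <- c(adj[[a]], i)
    adj[[b]] <- c(adj[[b]], i)
  }
  vapply(seq_len(nrow(bb)), function(k) {
    a <- bb[k, 1]; b <- bb[k, 2]
    seen <- rep(FALSE, n); seen[a] <- TRUE
    stack <- a
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bb[e, 1] == v) bb[e, 2] else bb[e, 1]
        if (!seen[w]) {
          if (w == b) return(TRUE)
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Standardize a molecule
#'
#' Optional normalizations applied after parsing: explicit polar hydrogens
#' (hydrogens on N, O and S are materialized as graph atoms) and canonical
#' tautomer selection (acyclic 1,3 keto-enol pairs are normalized to the
#' keto form; aromatic and ring bonds are left untouched). Disabled options
#' are no-ops; the result is deterministic.
#'
#' @param smiles a single valid SMILES string.
#' @param add_polar_h materialize polar hydrogens.
#' @param canonical_tautomer normalize acyclic enols to ketones.
#' @return an [ChemmineR::SDFset] with one molecule.
#' @export
standardize_molecule <- function(smiles, add_polar_h = FALSE,
                                 canonical_tautomer = FALSE) {
  sdfset <- parse_smiles(smiles, ids = "mol")
  sdf <- sdfset[[1]]

  if (canonical_tautomer) {
    repeat {
      el <- sdf_elements(sdf)
      ch <- sdf_charges(sdf)
      bb <- sdf@bondblock
      ring <- sdf_ring_bonds(sdf)
      deg <- tabulate(c(bb[, 1], bb[, 2]), nbins = length(el))
      hit <- NULL
      for (i in order(seq_along(el))) {
        if (el[i] != "O" || ch[i] != 0 || deg[i] != 1) next
        e1 <- which((bb[, 1] == i | bb[, 2] == i) & bb[, 3] == 1)
        if (length(e1) != 1L) next
        c1 <- if (bb[e1, 1] == i) bb[e1, 2] else bb[e1, 1]
        if (el[c1] != "C") next
        e2 <- which((bb[, 1] == c1 | bb[, 2] == c1) & bb[, 3] == 2 & !ring)
        for (e in e2) {
          c2 <- if (bb[e, 1] == c1) bb[e, 2] else bb[e, 1]
          if (el[c2] == "C") { hit <- c(oe = unname(e1), ce = unname(e)); break }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) break
      bb[hit["oe"], 3] <- 2
      bb[hit["ce"], 3] <- 1
      sdf@bondblock <- bb
    }
  }

  if (add_polar_h) {
    imp <- sdf_implicit_h(sdf)
    el <- sdf_elements(sdf)
    polar <- which(el %in% c("N", "O", "S") & imp > 0)
    ab <- sdf@atomblock
    bb <- sdf@bondblock
    for (i in polar) {
      for (k in seq_len(imp[i])) {
        newrow <- ab[1, , drop = FALSE] * 0
        rownames(newrow) <- sprintf("H_%d", nrow(ab) + 1L)
        ab <- rbind(ab, newrow)
        bnew <- bb[1, , drop = FALSE] * 0
        bnew[1, 1] <- i; bnew[1, 2] <- nrow(ab); bnew[1, 3] <- 1
        rownames(bnew) <- as.character(nrow(bb) + 1L)
        bb <- rbind(bb, bnew)
      }
    }
    sdf@atomblock <- ab
    sdf@bondblock <- bb
  }

  methods::new("SDFset", SDF = list(sdf), ID = "mol")
}

#' Count SMARTS substructure matches
#'
#' Entry (i, j) is the number of distinct atom sets of molecule i matched
#' by pattern j: symmetry-equivalent mappings of the same atom set count
#' once.
#'
#' @param mols an [ChemmineR::SDFset], or a character vector of SMILES.
#' @param patterns a `pattern_set` (see [load_pattern_set()]).
#' @return integer matrix, molecules x patterns.
#' @export
substructure_count <- function(mols, patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (is.character(mols))
    mols <- parse_smiles(mols, ids = make.unique(mols))
  counts <- vapply(seq_len(nrow(patterns)), function(j) {
    as.integer(ChemmineR::smartsSearchOB(mols, patterns$smarts[j],
                                         uniqueMatches = TRUE))
  }, integer(length(mols)))
  if (length(mols) == 1L) counts <- matrix(counts, nrow = 1L)
  dimnames(counts) <- list(ChemmineR::cid(mols), patterns$name)
  counts
}

#' Presence bits from substructure counts
#'
#' @param counts matrix or vector of non-negative counts.
#' @return same shape, bit j = 1 iff count j > 0.
#' @export
substructure_presence <- function(counts) {
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  (counts > 0) + 0L
}

#' Featurize a curated compound set
#'
#' Computes a fingerprint matrix over the pattern set, in input row order.
#' Compounds whose SMILES cannot be processed are excluded and reported in
#' the `failed` attribute; columns that are zero for every compound are
#' flagged in the `zero_variance` attribute.
#'
#' @param compounds data.frame with `canonical_smiles` (e.g. the
#'   `compounds` element of [curate()]'s result), or a character vector of
#'   SMILES.
#' @param patterns a `pattern_set`.
#' @param kind `"count"` or `"presence"`.
#' @param ids compound identifiers; defaults to `CMP00001`-style labels.
#' @return a [fingerprint_matrix()].
#' @export
featurize_dataset <- function(compounds, patterns,
                              kind = c("count", "presence"), ids = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(patterns, "pattern_set"))
  if (nrow(patterns) == 0L) stop("empty pattern set", call. = FALSE)
  smiles <- if (is.data.frame(compounds)) compounds$canonical_smiles
            else as.character(compounds)
  if (is.null(ids)) ids <- sprintf("CMP%05d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  ok <- vapply(smiles, function(s) smiles_tokenize(s)$ok, logical(1),
               USE.NAMES = FALSE)
  failed <- ids[!ok]
  sdf <- parse_smiles(smiles[ok], ids = ids[ok])
  counts <- substructure_count(sdf, patterns)
  if (kind == "presence") counts <- substructure_presence(counts)
  fp <- fingerprint_matrix(counts, kind = kind,
                           provenance = attr(patterns, "source_name"))
  attr(fp, "failed") <- failed
  attr(fp, "zero_variance") <-
    colnames(counts)[apply(counts, 2, function(x) all(x == 0))]
  fp
}

#' Lipinski rule-of-five profile
#'
#' Molecular weight and a Crippen-type additive logP from OpenBabel;
#' hydrogen-bond donors counted as N-H plus O-H hydrogens, acceptors as
#' nitrogen plus oxygen atoms (the classic rule-of-five conventions).
#' `violations` counts failed rules among mw < 500, logP < 5, HBA < 10,
#' HBD <= 5.
#'
#' @param smiles character vector of valid, desalted SMILES.
#' @return data.frame with columns mw, logp, hbd, hba, violations.
#' @export
ro5_profile <- function(smiles) {
  props <- ob_props(smiles)
  sdf <- parse_smiles(smiles, ids = sprintf("m%06d", seq_along(smiles)))
  hbd <- integer(length(smiles)); hba <- integer(length(smiles))
  for (i in seq_along(smiles)) {
    m <- sdf[[i]]
    el <- sdf_elements(m)
    imp <- sdf_implicit_h(m)
    # explicit hydrogens attached to N/O (rare in parsed SMILES) also count
    bb <- m@bondblock
    exp_h <- rep(0L, length(el))
    if (nrow(bb)) for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]; b <- bb[k, 2]
      if (el[a] == "H") exp_h[b] <- exp_h[b] + 1L
      if (el[b] == "H") exp_h[a] <- exp_h[a] + 1L
    }
    don <- el %in% c("N", "O")
    hbd[i] <- sum(imp[don] + exp_h[don])
    hba[i] <- sum(don)
  }
  out <- data.frame(mw = props$MW, logp = props$logP, hbd = hbd, hba = hba)
  out$violations <- ro5_violations(out$mw, out$logp, out$hbd, out$hba)
  rownames(out) <- NULL
  out
}

#' Count rule-of-five violations
#'
#' @param mw,logp,hbd,hba property vectors.
#' @return integer vector: failed rules among mw < 500, logP < 5,
#'   HBA < 10, HBD <= 5.
#' @export
ro5_violations <- function(mw, logp, hbd, hba) {
  as.integer((mw >= 500) + (logp >= 5) + (hba >= 10) + (hbd > 5))
}

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Graph descriptors without a SMARTS expression
#'
#' Native graph operations for descriptor classes that a pattern file
#' cannot express: the number of specified chiral centres (stereo atoms in
#' the canonical SMILES) and the rotatable-bond count (non-ring single
#' bonds between non-terminal heavy atoms, excluding bonds adjacent to a
#' triple bond).
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns `chiral_centers` and `rotatable_bonds`.
#' @export
graph_descriptors <- function(smiles) {
  can <- canonical_smiles(smiles)
  chiral <- vapply(can, function(s) {
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    sum(grepl("@", brackets, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)
  sdf <- parse_smiles(smiles, ids = sprintf("m%06d", seq_along(smiles)))
  rot <- as.integer(ChemmineR::smartsSearchOB(sdf, ROTATABLE_SMARTS,
                                              uniqueMatches = TRUE))
  data.frame(chiral_centers = chiral, rotatable_bonds = rot)
}

#' Import an externally computed descriptor matrix
#'
#' CSV adapter for fingerprint families computed outside the package
#' (PaDEL-style exports): first column compound id, remaining columns
#' numeric features.
#'
#' @param path CSV file.
#' @param kind `"count"` or `"presence"`.
#' @return a [fingerprint_matrix()] with provenance `"external"`.
#' @export
import_external_matrix <- function(path, kind = c("count", "presence")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected id column plus features", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  feats <- df[-1L]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col) || any(is.na(col))) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) | is.na(col))[1L]
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad, names(feats)[j]), call. = FALSE)
    }
  }
  values <- as.matrix(feats)
  rownames(values) <- ids
  fingerprint_matrix(values, kind = kind, provenance = "external")
}

#' Write a fingerprint matrix as CSV
#'
#' Inverse of [import_external_matrix()]: leading `compound_id` column,
#' then one column per feature.
#'
#' @param fp a [fingerprint_matrix()].
#' @param path CSV destination.
#' @return invisibly `path`.
#' @export
write_fingerprint_matrix <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  df <- data.frame(compound_id = fp$compound_ids,
                   as.data.frame(fp$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
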