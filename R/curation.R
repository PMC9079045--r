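# Curation of raw bioactivity tables: filtering on relation/confidence/
# assay-type, desalting, IC50 -> pIC50 conversion, and replicate
# deduplication, reducing the table to one pIC50 per unique desalted
# structure. Censored records (</>) are diverted to qualification sets
# rather than discarded.

#' Curation settings
#'
#' @param required_confidence ChEMBL confidence score a record must carry
#'   (default 9, a direct single protein target).
#' @param required_assay_type assay type code (default `"B"`, binding).
#' @param dedup_sd_threshold replicate groups whose pIC50 standard
#'   deviation exceeds this are discarded entirely ("value disagreement");
#'   groups at or below it collapse to their median. pIC50 units.
#' @param unit_policy `"strict_nM"` rejects any unit other than nM;
#'   `"convert_known_units"` additionally accepts pM, uM/µM and M.
#' @param predesalt_dedup also collapse records with identical raw SMILES
#'   before desalting (two-pass deduplication).
#' @return an object of class `curation_config`.
#' @export
curation_config <- function(required_confidence = 9L,
                            required_assay_type = "B",
                            dedup_sd_threshold = 1.0,
                            unit_policy = c("strict_nM",
                                            "convert_known_units"),
                            predesalt_dedup = FALSE) {
  unit_policy <- match.arg(unit_policy)
  if (dedup_sd_threshold <= 0)
    stop("dedup_sd_threshold must be > 0", call. = FALSE)
  structure(list(required_confidence = as.integer(required_confidence),
                 required_assay_type = required_assay_type,
                 dedup_sd_threshold = dedup_sd_threshold,
                 unit_policy = unit_policy,
                 predesalt_dedup = isTRUE(predesalt_dedup)),
            class = "curation_config")
}

#' Read a ChEMBL-style activity table
#'
#' CSV/TSV with at least the columns molecule_id, canonical_smiles,
#' standard_value, standard_units, standard_relation, confidence_score,
#' assay_type, assay_id. Extra columns are ignored.
#'
#' @param path file path; the separator is sniffed from the header line.
#' @return data.frame of raw activity records.
#' @export
read_activity_table <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("molecule_id", "canonical_smiles", "standard_value",
            "standard_units", "standard_relation", "confidence_score",
            "assay_type", "assay_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("activity table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' Filter raw activity records
#'
#' Partitions the table into records kept for regression modelling
#' (relation `=`, required confidence and assay type, non-missing value),
#' censored records diverted for qualification (`<`/`>`, same confidence
#' and assay-type requirements), and dropped records, each annotated with
#' the first rule that removed it.
#'
#' @param table data.frame of raw records (see [read_activity_table()]).
#' @param cfg a [curation_config()].
#' @return list with `kept`, `censored` and `dropped` data.frames; `dropped`
#'   carries a `drop_rule` column. The three partition the input rows.
#' @export
filter_records <- function(table, cfg = curation_config()) {
  stopifnot(is.data.frame(table), inherits(cfg, "curation_config"))
  if (nrow(table) == 0L)
    return(list(kept = table, censored = table,
                dropped = cbind(table, drop_rule = character(0))))
  rule <- rep(NA_character_, nrow(table))
  rel <- as.character(table$standard_relation)
  bad_rel <- !(rel %in% c("=", "<", ">")) | is.na(rel)
  rule[bad_rel] <- "unknown_relation"
  f <- is.na(rule) & table$confidence_score != cfg$required_confidence
  rule[f] <- "confidence"
  f <- is.na(rule) & table$assay_type != cfg$required_assay_type
  rule[f] <- "assay_type"
  f <- is.na(rule) & is.na(table$standard_value)
  rule[f] <- "missing_value"
  f <- is.na(rule) & table$standard_value <= 0
  rule[f] <- "nonpositive_value"
  keep <- is.na(rule) & rel == "="
  cens <- is.na(rule) & rel %in% c("<", ">")
  drop <- !is.na(rule)
  dropped <- table[drop, , drop = FALSE]
  dropped$drop_rule <- rule[drop]
  list(kept = table[keep, , drop = FALSE],
       censored = table[cens, , drop = FALSE],
       dropped = dropped)
}

#' Strip counter-ions from a SMILES string
#'
#' Keeps the fragment with the most heavy atoms; ties are broken by larger
#' molecular weight, then by lexicographically smallest canonical SMILES.
#' The result is returned in canonical form and always has one fragment.
#'
#' @param smiles character vector of valid SMILES (may contain `.`).
#' @return character vector of canonical single-fragment SMILES.
#' @export
desalt <- function(smiles) {
  vapply(smiles, function(s) {
    frs <- smiles_fragments(s)
    if (length(frs) == 1L) return(canonical_smiles(frs))
    hv <- heavy_atom_count(frs)
    if (max(hv) == 0L)
      stop(sprintf("all fragments of '%s' have zero heavy atoms", s),
           call. = FALSE)
    cand <- frs[hv == max(hv)]
    if (length(cand) > 1L) {
      mw <- mol_weight(cand)
      cand <- cand[mw == max(mw)]
    }
    if (length(cand) > 1L) cand <- sort(canonical_smiles(cand))
    canonical_smiles(cand[1L])
  }, character(1), USE.NAMES = FALSE)
}

# decimal exponent of each unit relative to mol/L (nM = 10^-9 M, ...)
UNIT_EXPONENT <- c(nM = 9, pM = 12, uM = 6, `µM` = 6, M = 0)

#' Convert a concentration to pIC50
#'
#' `-log10` of the value expressed in mol/L; for nM this is
#' `9 - log10(value)`.
#'
#' @param value positive concentration(s).
#' @param units unit string(s); `"nM"` always accepted, other known units
#'   (pM, uM, M) only under `unit_policy = "convert_known_units"`.
#' @param unit_policy see [curation_config()].
#' @return numeric vector of pIC50 values.
#' @export
to_pic50 <- function(value, units = "nM", unit_policy = "strict_nM") {
  if (any(is.na(value)) || any(value <= 0))
    stop("pIC50 undefined for missing or non-positive concentrations",
         call. = FALSE)
  units <- rep_len(as.character(units), length(value))
  allowed <- if (identical(unit_policy, "strict_nM")) "nM"
             else names(UNIT_EXPONENT)
  bad <- !(units %in% allowed)
  if (any(bad))
    stop(sprintf("unrecognized units under %s: %s", unit_policy,
                 paste(unique(units[bad]), collapse = ", ")), call. = FALSE)
  unname(UNIT_EXPONENT[units] - log10(value))
}

#' Inverse of [to_pic50()]
#'
#' @param pic50 numeric vector of pIC50 values.
#' @param units target concentration unit.
#' @return concentrations in `units`.
#' @export
pic50_to_value <- function(pic50, units = "nM") {
  if (!all(units %in% names(UNIT_EXPONENT)))
    stop("unknown units", call. = FALSE)
  unname(10^(UNIT_EXPONENT[rep_len(units, length(pic50))] - pic50))
}

#' Collapse replicate measurements of the same structure
#'
#' Records are grouped by exact canonical SMILES equality. Singletons pass
#' through. A replicate group collapses to its median pIC50 when the group
#' standard deviation is at or below `cfg$dedup_sd_threshold`; otherwise
#' the whole group is removed as a value disagreement.
#'
#' @param records data.frame with columns `canonical_smiles`, `pic50`, and
#'   optionally provenance columns `molecule_id`, `assay_id`.
#' @param cfg a [curation_config()].
#' @return list with `compounds` (canonical_smiles, pic50,
#'   n_source_records, source_ids) and `removed` (audit of discarded
#'   groups with reason).
#' @export
deduplicate <- function(records, cfg = curation_config()) {
  stopifnot(is.data.frame(records),
            all(c("canonical_smiles", "pic50") %in% names(records)))
  if (any(!is.finite(records$pic50)))
    stop("non-finite pIC50 before deduplication", call. = FALSE)
  empty <- data.frame(canonical_smiles = character(0), pic50 = numeric(0),
                      n_source_records = integer(0),
                      source_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    return(list(compounds = empty, removed = records[0, , drop = FALSE]))
  src <- if (all(c("molecule_id", "assay_id") %in% names(records))) {
    paste(records$molecule_id, records$assay_id, sep = "/")
  } else as.character(seq_len(nrow(records)))
  groups <- split(seq_len(nrow(records)), records$canonical_smiles)
  keep <- list(); removed_idx <- integer(0)
  for (g in groups) {
    pic <- records$pic50[g]
    if (length(g) == 1L || sd(pic) <= cfg$dedup_sd_threshold) {
      keep[[length(keep) + 1L]] <- data.frame(
        canonical_smiles = records$canonical_smiles[g[1L]],
        pic50 = median(pic),
        n_source_records = length(g),
        source_ids = paste(src[g], collapse = ";"),
        stringsAsFactors = FALSE)
    } else {
      removed_idx <- c(removed_idx, g)
    }
  }
  compounds <- if (length(keep)) do.call(rbind, keep) else empty
  compounds <- compounds[order(compounds$canonical_smiles), , drop = FALSE]
  rownames(compounds) <- NULL
  removed <- records[removed_idx, , drop = FALSE]
  if (nrow(removed)) removed$drop_rule <- "value disagreement"
  list(compounds = compounds, removed = removed)
}

# Internal: uniform audit record.
audit_entry <- function(df, rule) {
  if (nrow(df) == 0L)
    return(data.frame(molecule_id = character(0), assay_id = character(0),
                      drop_rule = character(0), stringsAsFactors = FALSE))
  data.frame(molecule_id = as.character(df$molecule_id),
             assay_id = as.character(df$assay_id),
             drop_rule = if (length(rule) == 1L) rep(rule, nrow(df)) else rule,
             stringsAsFactors = FALSE)
}

# Internal: desalt a column of raw SMILES with per-row error capture.
# Unique strings are desalted once and the result reused.
desalt_rows <- function(df) {
  if (nrow(df) == 0L) {
    df$desalted <- character(0)
    return(list(ok = df, bad = df[0, , drop = FALSE]))
  }
  uniq <- unique(df$canonical_smiles)
  res <- stats::setNames(rep(NA_character_, length(uniq)), uniq)
  ok_syntax <- vapply(uniq, function(s) smiles_tokenize(s)$ok, logical(1))
  plain <- ok_syntax & !grepl(".", uniq, fixed = TRUE)
  if (any(plain))  # salt-free strings canonicalize in one batched call
    res[plain] <- tryCatch(canonical_smiles(uniq[plain]),
                           error = function(e) rep(NA_character_,
                                                   sum(plain)))
  for (s in uniq[ok_syntax & !plain])
    res[s] <- tryCatch(desalt(s), error = function(e) NA_character_)
  mapped <- res[df$canonical_smiles]
  bad <- is.na(mapped)
  okdf <- df[!bad, , drop = FALSE]
  okdf$desalted <- unname(mapped[!bad])
  list(ok = okdf, bad = df[bad, , drop = FALSE])
}

#' Curate a raw activity table
#'
#' Full curation pipeline: [filter_records()], per-row [desalt()] and
#' [to_pic50()] conversion (row-level failures are audited, never fatal),
#' then [deduplicate()]. Censored rows are desalted and converted to
#' bound pIC50 values, split by relation sign.
#'
#' @param table data.frame of raw records.
#' @param cfg a [curation_config()].
#' @return object of class `curation_result`: list with `compounds`
#'   (one row per unique structure), `gt_set` / `lt_set` (censored
#'   records, relation on the IC50 concentration scale), `report` (row
#'   counts after every stage) and `audit` (all dropped rows with the rule
#'   that removed each).
#' @export
curate <- function(table, cfg = curation_config()) {
  flt <- filter_records(table, cfg)
  audit <- audit_entry(flt$dropped, flt$dropped$drop_rule)
  kept <- flt$kept

  stage_counts <- c(input = nrow(table),
                    kept_after_filter = nrow(kept),
                    censored_after_filter = nrow(flt$censored))

  if (cfg$predesalt_dedup && nrow(kept) > 0L) {
    pic <- vapply(seq_len(nrow(kept)), function(i)
      tryCatch(to_pic50(kept$standard_value[i], kept$standard_units[i],
                        cfg$unit_policy), error = function(e) NA_real_),
      numeric(1))
    groups <- split(seq_len(nrow(kept)), kept$canonical_smiles)
    keep_rows <- unlist(lapply(groups, function(g) {
      if (length(g) == 1L || any(is.na(pic[g]))) return(g)
      if (sd(pic[g]) <= cfg$dedup_sd_threshold)
        g[which.min(abs(pic[g] - median(pic[g])))]
      else integer(0)
    }), use.names = FALSE)
    drop_rows <- setdiff(seq_len(nrow(kept)), keep_rows)
    if (length(drop_rows))
      audit <- rbind(audit, audit_entry(kept[drop_rows, , drop = FALSE],
                                        "predesalt_duplicate"))
    kept <- kept[sort(keep_rows), , drop = FALSE]
  }

  ds <- desalt_rows(kept)
  if (nrow(ds$bad))
    audit <- rbind(audit, audit_entry(ds$bad, "desalt_error"))
  kept <- ds$ok
  stage_counts["after_desalt"] <- nrow(kept)

  if (nrow(kept) > 0L) {
    pic <- vapply(seq_len(nrow(kept)), function(i)
      tryCatch(to_pic50(kept$standard_value[i], kept$standard_units[i],
                        cfg$unit_policy), error = function(e) NA_real_),
      numeric(1))
    bad <- is.na(pic)
    if (any(bad))
      audit <- rbind(audit, audit_entry(kept[bad, , drop = FALSE],
                                        "unit_error"))
    kept <- kept[!bad, , drop = FALSE]
    kept$pic50 <- pic[!bad]
  } else {
    kept$pic50 <- numeric(0)
  }
  stage_counts["after_conversion"] <- nrow(kept)

  rec <- data.frame(canonical_smiles = kept$desalted,
                    pic50 = kept$pic50,
                    molecule_id = kept$molecule_id,
                    assay_id = kept$assay_id,
                    stringsAsFactors = FALSE)
  dd <- deduplicate(rec, cfg)
  if (nrow(dd$removed))
    audit <- rbind(audit, audit_entry(dd$removed, "value disagreement"))
  stage_counts["compounds"] <- nrow(dd$compounds)

  cens <- desalt_rows(flt$censored)
  if (nrow(cens$bad))
    audit <- rbind(audit, audit_entry(cens$bad, "desalt_error"))
  cdf <- cens$ok
  if (nrow(cdf) > 0L) {
    bound <- vapply(seq_len(nrow(cdf)), function(i)
      tryCatch(to_pic50(cdf$standard_value[i], cdf$standard_units[i],
                        cfg$unit_policy), error = function(e) NA_real_),
      numeric(1))
    ok <- !is.na(bound)
    if (any(!ok))
      audit <- rbind(audit, audit_entry(cdf[!ok, , drop = FALSE],
                                        "unit_error"))
    cdf <- cdf[ok, , drop = FALSE]
    cdf$bound_pic50 <- bound[ok]
  } else {
    cdf$bound_pic50 <- numeric(0)
  }
  make_censored <- function(df) {
    data.frame(canonical_smiles = df$desalted,
               bound_pic50 = df$bound_pic50,
               relation = df$standard_relation,
               assay_id = df$assay_id,
               stringsAsFactors = FALSE)
  }
  gt_set <- make_censored(cdf[cdf$standard_relation == ">", , drop = FALSE])
  lt_set <- make_censored(cdf[cdf$standard_relation == "<", , drop = FALSE])
  stage_counts["gt_set"] <- nrow(gt_set)
  stage_counts["lt_set"] <- nrow(lt_set)
  rownames(audit) <- NULL

  structure(list(compounds = dd$compounds,
                 gt_set = gt_set, lt_set = lt_set,
                 report = as.list(stage_counts),
                 audit = audit),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("Curation result\n")
  for (nm in names(x$report))
    cat(sprintf("  %-22s %d\n", nm, x$report[[nm]]))
  invisible(x)
}

#' Write curated compounds to CSV (and optionally SDF)
#'
#' @param result a `curation_result`.
#' @param csv_path CSV destination (canonical_smiles, pic50,
#'   n_source_records).
#' @param sdf_path optional SDF destination with pIC50 as a property.
#' @param audit_path optional JSON audit destination.
#' @return invisibly `csv_path`.
#' @export
write_curated <- function(result, csv_path, sdf_path = NULL,
                          audit_path = NULL) {
  stopifnot(inherits(result, "curation_result"))
  cols <- c("canonical_smiles", "pic50", "n_source_records")
  write.csv(result$compounds[cols], csv_path, row.names = FALSE)
  if (!is.null(sdf_path) && nrow(result$compounds)) {
    sdf <- parse_smiles(result$compounds$canonical_smiles,
                        ids = sprintf("CMP%05d",
                                      seq_len(nrow(result$compounds))))
    for (i in seq_along(ChemmineR::cid(sdf))) {
      sdf[[i]]@datablock <- c(pIC50 =
                                format(result$compounds$pic50[i], digits = 10))
    }
    ChemmineR::write.SDF(sdf, sdf_path)
  }
  if (!is.null(audit_path))
    jsonlite::write_json(result$audit, audit_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
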