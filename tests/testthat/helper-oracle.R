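# Independent brute-force substructure-matching oracle.
#
# A miniature SMILES reader and SMARTS matcher written from first
# principles, sharing no code with the package's OpenBabel-backed
# implementation. It supports the restricted SMARTS grammar used by the
# bundled pattern set (element/aromatic primitives, #n, X/D/H/R, charges,
# !, &, comma and semicolon booleans; bonds - = # : ~ and the
# single-or-aromatic default) and counts unique matched atom sets by
# exhaustive backtracking.

oracle_valence <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                       S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

# --- SMILES -> molecular graph --------------------------------------------

oracle_parse_smiles <- function(s) {
  chars <- strsplit(s, "")[[1]]
  atoms <- list()   # elem, aromatic, charge, hcount (NA = implicit)
  bonds <- list()   # a, b, sym ("" default, "-", "=", "#", ":")
  prev <- NA_integer_
  stack <- integer(0)
  pend <- ""
  ring <- list()
  i <- 1L; n <- length(chars)
  add_atom <- function(elem, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(elem = elem, aromatic = aromatic,
                                         charge = charge, hcount = hcount)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, sym = sym)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      content <- gsub("^[0-9]+", "", content)          # isotope
      m <- regexpr("^([A-Za-z][a-z]?)", content)
      elem_raw <- regmatches(content, m)
      rest <- substr(content, attr(m, "match.length") + 1L, nchar(content))
      rest <- gsub("@+", "", rest)                      # stereo
      hcount <- 0L
      hm <- regexpr("H[0-9]*", rest)
      if (hm > 0) {
        htok <- regmatches(rest, hm)
        hcount <- if (htok == "H") 1L else as.integer(substring(htok, 2L))
        rest <- sub("H[0-9]*", "", rest)
      }
      charge <- 0L
      cm <- regexpr("[+-][0-9]*", rest)
      if (cm > 0) {
        ctok <- regmatches(rest, cm)
        sign <- if (startsWith(ctok, "+")) 1L else -1L
        num <- substring(ctok, 2L)
        charge <- sign * (if (nzchar(num)) as.integer(num) else
          nchar(gsub("[^+-]", "", rest)))
      }
      aromatic <- elem_raw %in% c("c", "n", "o", "s", "p", "b")
      elem <- if (aromatic) paste0(toupper(substring(elem_raw, 1, 1)),
                                   substring(elem_raw, 2)) else elem_raw
      idx <- add_atom(elem, aromatic, charge, hcount)
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), FALSE)
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE)
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pend <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pend <- "-"; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      num <- if (ch == "%") {
        i <- i + 2L
        paste(chars[(i - 1L):i], collapse = "")
      } else ch
      key <- as.character(as.integer(num))
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pend)
      } else {
        sym <- if (nzchar(pend)) pend else ring[[key]]$sym
        add_bond(ring[[key]]$atom, prev, sym)
        ring[[key]] <- NULL
      }
      pend <- ""
      i <- i + 1L
    } else stop("oracle: unexpected character ", ch)
  }

  na <- length(atoms)
  elem <- vapply(atoms, `[[`, character(1), "elem")
  aromatic <- vapply(atoms, `[[`, logical(1), "aromatic")
  charge <- vapply(atoms, `[[`, integer(1), "charge")
  hexp <- vapply(atoms, function(a) a$hcount, integer(1))

  nb <- length(bonds)
  ba <- vapply(bonds, `[[`, integer(1), "a")
  bb <- vapply(bonds, `[[`, integer(1), "b")
  bsym <- vapply(bonds, `[[`, character(1), "sym")
  barom <- bsym == ":" | (bsym == "" & aromatic[ba] & aromatic[bb])
  border <- ifelse(bsym == "=", 2, ifelse(bsym == "#", 3, 1))

  # implicit hydrogens for organic-subset atoms (hcount NA)
  bsum <- rep(0, na); deg <- rep(0L, na)
  for (k in seq_len(nb)) {
    o <- if (barom[k]) 1 else border[k]
    bsum[ba[k]] <- bsum[ba[k]] + o; bsum[bb[k]] <- bsum[bb[k]] + o
    deg[ba[k]] <- deg[ba[k]] + 1L; deg[bb[k]] <- deg[bb[k]] + 1L
  }
  hyd <- hexp
  for (v in seq_len(na)) {
    if (!is.na(hexp[v])) next
    vals <- oracle_valence[[elem[v]]]
    if (is.null(vals)) { hyd[v] <- 0L; next }
    if (aromatic[v]) {
      # lowercase atoms stay at their lowest valence; the delocalized pi
      # system consumes one bonding slot
      hyd[v] <- max(0L, as.integer(min(vals) - bsum[v] - 1))
    } else {
      cand <- vals[vals >= bsum[v]]
      hyd[v] <- if (length(cand)) as.integer(min(cand) - bsum[v]) else 0L
    }
  }

  # ring bonds: removing the bond leaves endpoints connected
  in_ring_bond <- rep(FALSE, nb)
  if (nb) {
    adj <- lapply(seq_len(na), function(v) integer(0))
    for (k in seq_len(nb)) {
      adj[[ba[k]]] <- c(adj[[ba[k]]], k)
      adj[[bb[k]]] <- c(adj[[bb[k]]], k)
    }
    for (k in seq_len(nb)) {
      seen <- rep(FALSE, na); seen[ba[k]] <- TRUE
      st <- ba[k]; found <- FALSE
      while (length(st) && !found) {
        v <- st[length(st)]; st <- st[-length(st)]
        for (e in adj[[v]]) {
          if (e == k) next
          w <- if (ba[e] == v) bb[e] else ba[e]
          if (w == bb[k]) { found <- TRUE; break }
          if (!seen[w]) { seen[w] <- TRUE; st <- c(st, w) }
        }
      }
      in_ring_bond[k] <- found
    }
  }
  in_ring <- rep(FALSE, na)
  in_ring[c(ba[in_ring_bond], bb[in_ring_bond])] <- TRUE

  list(elem = elem, aromatic = aromatic, charge = charge, hyd = hyd,
       degree = deg, in_ring = in_ring,
       bond_a = ba, bond_b = bb, bond_order = border,
       bond_aromatic = barom)
}

# --- SMARTS -> pattern graph ----------------------------------------------

ELEMENT_BY_NUMBER <- c(`5` = "B", `6` = "C", `7` = "N", `8` = "O",
                       `9` = "F", `15` = "P", `16` = "S", `17` = "Cl",
                       `35` = "Br", `53` = "I")

# A primitive is a list(type, value, negate); an atom expression is a list
# of OR-groups (semicolon = AND), each OR-group a list of AND-chains
# (comma), each AND-chain a list of primitives (&).
oracle_parse_atom_expr <- function(content) {
  parse_primitives <- function(txt) {
    prims <- list(); i <- 1L; nn <- nchar(txt)
    while (i <= nn) {
      neg <- FALSE
      while (substring(txt, i, i) == "!") { neg <- !neg; i <- i + 1L }
      rest <- substring(txt, i)
      m <- regexpr(paste0("^(#[0-9]+|Cl|Br|[XDHR][0-9]*|\\+[0-9]*|",
                          "-[0-9]*|[A-IK-PR-Zacnops*])"), rest)
      if (m < 0) stop("oracle: cannot parse SMARTS primitives: ", txt)
      tok <- regmatches(rest, m)
      i <- i + attr(m, "match.length")
      prim <- if (startsWith(tok, "#")) {
        list(type = "elem_any", value = ELEMENT_BY_NUMBER[substring(tok, 2L)])
      } else if (tok %in% c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F",
                            "I")) {
        list(type = "elem_aliph", value = tok)
      } else if (tok %in% c("c", "n", "o", "p", "s", "b")) {
        list(type = "elem_arom",
             value = paste0(toupper(substring(tok, 1, 1)),
                            substring(tok, 2)))
      } else if (tok == "*") {
        list(type = "any")
      } else if (tok == "a") {
        list(type = "aromatic")
      } else if (tok == "A") {
        list(type = "aliphatic")
      } else if (grepl("^[XDHR]", tok)) {
        num <- substring(tok, 2L)
        list(type = substring(tok, 1L, 1L),
             value = if (nzchar(num)) as.integer(num) else NA_integer_)
      } else if (grepl("^[+-]", tok)) {
        num <- substring(tok, 2L)
        sign <- if (startsWith(tok, "+")) 1L else -1L
        list(type = "charge",
             value = sign * (if (nzchar(num)) as.integer(num) else 1L))
      } else stop("oracle: unknown primitive ", tok)
      prim$negate <- neg
      prims[[length(prims) + 1L]] <- prim
    }
    prims
  }
  lapply(strsplit(content, ";", fixed = TRUE)[[1]], function(andgrp) {
    lapply(strsplit(andgrp, ",", fixed = TRUE)[[1]], function(orterm) {
      unlist(lapply(strsplit(orterm, "&", fixed = TRUE)[[1]],
                    parse_primitives), recursive = FALSE)
    })
  })
}

oracle_parse_smarts <- function(p) {
  chars <- strsplit(p, "")[[1]]
  atoms <- list(); bonds <- list()
  prev <- NA_integer_; stack <- integer(0); pend <- ""; ring <- list()
  i <- 1L; n <- length(chars)
  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, sym = sym)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L; depth <- 1L
      while (depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        if (depth > 0L) j <- j + 1L
      }
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      idx <- add_atom(oracle_parse_atom_expr(content))
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(oracle_parse_atom_expr(paste0(ch, chars[i + 1L])))
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s", "a", "A", "*")) {
      idx <- add_atom(oracle_parse_atom_expr(ch))
      if (!is.na(prev)) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pend <- ch; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pend)
      } else {
        sym <- if (nzchar(pend)) pend else ring[[key]]$sym
        add_bond(ring[[key]]$atom, prev, sym)
        ring[[key]] <- NULL
      }
      pend <- ""
      i <- i + 1L
    } else stop("oracle: unexpected SMARTS character ", ch)
  }
  list(atoms = atoms,
       bond_a = vapply(bonds, `[[`, integer(1), "a"),
       bond_b = vapply(bonds, `[[`, integer(1), "b"),
       bond_sym = vapply(bonds, `[[`, character(1), "sym"))
}

# --- evaluation and matching ----------------------------------------------

oracle_atom_ok <- function(mol, v, expr) {
  prim_ok <- function(prim) {
    val <- switch(prim$type,
      any = TRUE,
      aromatic = mol$aromatic[v],
      aliphatic = !mol$aromatic[v],
      elem_any = mol$elem[v] == prim$value,
      elem_aliph = mol$elem[v] == prim$value && !mol$aromatic[v],
      elem_arom = mol$elem[v] == prim$value && mol$aromatic[v],
      X = (mol$degree[v] + mol$hyd[v]) ==
        (if (is.na(prim$value)) 1L else prim$value),
      D = mol$degree[v] == (if (is.na(prim$value)) 1L else prim$value),
      H = mol$hyd[v] == (if (is.na(prim$value)) 1L else prim$value),
      R = if (!is.na(prim$value) && prim$value == 0L) !mol$in_ring[v]
          else mol$in_ring[v],
      charge = mol$charge[v] == prim$value,
      stop("oracle: unhandled primitive ", prim$type))
    if (prim$negate) !val else val
  }
  all(vapply(expr, function(andgrp) {
    any(vapply(andgrp, function(chain) {
      all(vapply(chain, prim_ok, logical(1)))
    }, logical(1)))
  }, logical(1)))
}

oracle_bond_ok <- function(mol, bond_idx, sym) {
  arom <- mol$bond_aromatic[bond_idx]
  ord <- mol$bond_order[bond_idx]
  switch(sym,
         `~` = TRUE,
         `-` = !arom && ord == 1,
         `=` = !arom && ord == 2,
         `#` = !arom && ord == 3,
         `:` = arom,
         (!arom && ord == 1) || arom)   # default: single or aromatic
}

# Count unique matched atom sets of a SMARTS pattern in a molecule.
oracle_count <- function(smiles, smarts) {
  mol <- oracle_parse_smiles(smiles)
  pat <- oracle_parse_smarts(smarts)
  np <- length(pat$atoms)
  nm <- length(mol$elem)
  if (np == 0L || nm < np) return(0L)

  bond_lookup <- new.env()
  nb <- length(mol$bond_a)
  for (k in seq_len(nb)) {
    assign(paste(mol$bond_a[k], mol$bond_b[k]), k, envir = bond_lookup)
    assign(paste(mol$bond_b[k], mol$bond_a[k]), k, envir = bond_lookup)
  }
  # pattern adjacency: for atom j, bonds to already-placed atoms (< j)
  pat_edges <- lapply(seq_len(np), function(j) {
    sel <- which((pat$bond_a == j & pat$bond_b < j) |
                 (pat$bond_b == j & pat$bond_a < j))
    lapply(sel, function(e) list(
      other = if (pat$bond_a[e] == j) pat$bond_b[e] else pat$bond_a[e],
      sym = pat$bond_sym[e]))
  })
  cand <- lapply(seq_len(np), function(j) {
    which(vapply(seq_len(nm), function(v)
      oracle_atom_ok(mol, v, pat$atoms[[j]]), logical(1)))
  })
  sets <- character(0)
  assign_next <- function(j, mapping) {
    if (j > np) {
      sets <<- c(sets, paste(sort(mapping), collapse = " "))
      return(invisible())
    }
    for (v in cand[[j]]) {
      if (v %in% mapping) next
      ok <- TRUE
      for (e in pat_edges[[j]]) {
        bidx <- mget(paste(v, mapping[e$other]), envir = bond_lookup,
                     ifnotfound = list(NULL))[[1]]
        if (is.null(bidx) || !oracle_bond_ok(mol, bidx, e$sym)) {
          ok <- FALSE; break
        }
      }
      # every pattern bond must exist between mapped atoms; also check
      # bonds from j to later atoms are handled when those are placed
      if (ok) assign_next(j + 1L, c(mapping, v))
    }
  }
  assign_next(1L, integer(0))
  length(unique(sets))
}
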