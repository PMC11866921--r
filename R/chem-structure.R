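# Structure handling: molecules are parsed from SMILES into a heavy-atom
# graph (implicit hydrogens stored per atom). OpenBabel (via ChemmineOB) is
# used to validate and canonicalize input SMILES — the canonical aromatic
# form is what the reader consumes — and to supply InChI keys and log P.
# Fingerprints, similarity and the MCS-based fit metric are computed on the
# graph itself.

.tp_cache <- new.env(parent = emptyenv())

ob_convert <- function(smiles, to = "CAN") {
  out <- vapply(smiles, function(s) {
    r <- tryCatch(ChemmineOB::convertFormat("SMI", to, s), error = function(e) "")
    r <- strsplit(r, "[\t\n]")[[1]]
    if (length(r) == 0L || !nzchar(r[1])) NA_character_ else r[1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Canonical SMILES
#'
#' Canonicalizes a SMILES string with OpenBabel. Fails with a named error
#' when the string does not parse.
#'
#' @param smiles SMILES string(s).
#' @return Canonical SMILES string(s).
#' @export
canonical_smiles <- function(smiles) {
  key <- paste0("can:", smiles)
  hit <- vapply(key, function(k) exists(k, envir = .tp_cache), logical(1))
  out <- character(length(smiles))
  out[hit] <- vapply(key[hit], function(k) get(k, envir = .tp_cache), character(1))
  if (any(!hit)) {
    res <- ob_convert(smiles[!hit], "CAN")
    bad <- is.na(res)
    if (any(bad))
      stop("unparseable SMILES: ", paste(smiles[!hit][bad], collapse = ", "))
    for (i in seq_along(res)) assign(key[!hit][i], res[i], envir = .tp_cache)
    out[!hit] <- res
  }
  out
}

#' Connectivity key
#'
#' First (connectivity) block of the standard InChI key; stereoisomers that
#' differ only in the stereo layer share the same key, which is the
#' deduplication key for structure suspects.
#'
#' @param smiles SMILES string(s).
#' @return 14-character key(s); `NA` for unparseable input.
#' @export
inchikey_block <- function(smiles) {
  vapply(smiles, function(s) {
    k <- paste0("ik:", s)
    if (exists(k, envir = .tp_cache)) return(get(k, envir = .tp_cache))
    r <- ob_convert(s, "INCHIKEY")
    r <- if (is.na(r)) NA_character_ else substr(r, 1, 14)
    assign(k, r, envir = .tp_cache)
    r
  }, character(1), USE.NAMES = FALSE)
}

# ---- SMILES reader ---------------------------------------------------------

.organic_valence <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a heavy-atom graph
#'
#' The string is first canonicalized with OpenBabel (so aromaticity is
#' perceived consistently across inputs), then read into a graph with one
#' node per heavy atom. Implicit hydrogen counts follow the SMILES valence
#' conventions. Stereo descriptors are ignored; disconnected (dot) SMILES
#' are rejected.
#'
#' @param smiles A SMILES string.
#' @param canonicalize Canonicalize via OpenBabel first (default TRUE).
#' @return A `tp_mol`: list with `atoms` (element, aromatic, charge, nH),
#'   `bonds` (a1, a2, order; aromatic bonds have order 1.5) and the
#'   canonical `smiles`.
#' @export
mol_from_smiles <- function(smiles, canonicalize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- if (canonicalize) canonical_smiles(smiles) else smiles
  ck <- paste0("mol:", can)
  if (exists(ck, envir = .tp_cache)) return(get(ck, envir = .tp_cache))
  s <- can
  n <- nchar(s)
  el <- character(0); arom <- logical(0); chg <- integer(0); exH <- integer(0)
  bnd <- matrix(numeric(0), ncol = 3)
  prev <- integer(0)            # branch stack; last element = current atom
  pend <- NA_real_              # pending bond order
  rings <- list()               # ring-closure bookkeeping
  i <- 1L
  add_atom <- function(sym, ar, charge = 0L, hcount = NA_integer_) {
    el[[length(el) + 1L]] <<- sym
    arom[[length(arom) + 1L]] <<- ar
    chg[[length(chg) + 1L]] <<- charge
    exH[[length(exH) + 1L]] <<- hcount
    idx <- length(el)
    if (length(prev)) {
      a <- prev[length(prev)]
      o <- if (!is.na(pend)) pend else if (arom[a] && ar) 1.5 else 1
      bnd <<- rbind(bnd, c(a, idx, o))
    }
    prev[length(prev) + (if (length(prev)) 0L else 1L)] <<- idx
    pend <<- NA_real_
    idx
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom in SMILES '", s, "'")
      body <- substr(s, i + 1L, i + j - 2L)
      i <- i + j
      body <- gsub("^[0-9]+", "", body)            # isotope label ignored
      m <- regmatches(body, regexec("^([A-Za-z][a-z]?)", body))[[1]]
      sym <- m[2]
      rest <- substr(body, nchar(sym) + 1L, nchar(body))
      rest <- gsub("@+[A-Z]*[0-9]*", "", rest)     # stereo ignored
      hc <- 0L
      hm <- regmatches(rest, regexec("H([0-9]*)", rest))[[1]]
      if (length(hm)) hc <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      charge <- 0L
      cm <- regmatches(rest, regexec("([+-])([0-9]*)", rest))[[1]]
      if (length(cm)) {
        mag <- if (nzchar(cm[3])) as.integer(cm[3]) else
          nchar(gsub("[^+-]", "", rest))
        charge <- if (cm[2] == "+") mag else -mag
      }
      ar <- sym == tolower(sym) && nchar(sym) == 1L
      sym2 <- if (ar) toupper(sym) else sym
      add_atom(sym2, ar, charge, hc)
    } else if (ch %in% c("C", "B", "N", "O", "S", "P", "F", "I")) {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) { add_atom(two, FALSE); i <- i + 1L }
      else add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("c", "b", "n", "o", "s", "p")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) { pend <- 1; i <- i + 1L
    } else if (ch == "=") { pend <- 2; i <- i + 1L
    } else if (ch == "#") { pend <- 3; i <- i + 1L
    } else if (ch == ":") { pend <- 1.5; i <- i + 1L
    } else if (ch == "(") {
      prev <- c(prev, prev[length(prev)]); i <- i + 1L
    } else if (ch == ")") {
      prev <- prev[-length(prev)]; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { lab <- substr(s, i + 1L, i + 2L); i <- i + 3L }
      else { lab <- ch; i <- i + 1L }
      cur <- prev[length(prev)]
      if (!is.null(rings[[lab]])) {
        op <- rings[[lab]]
        o <- if (!is.na(pend)) pend else if (!is.na(op$order)) op$order else
          if (arom[op$atom] && arom[cur]) 1.5 else 1
        bnd <- rbind(bnd, c(op$atom, cur, o))
        rings[[lab]] <- NULL
        pend <- NA_real_
      } else {
        rings[[lab]] <- list(atom = cur, order = pend)
        pend <- NA_real_
      }
    } else if (ch == ".") {
      stop("disconnected (dot) SMILES not supported: '", s, "'")
    } else stop("unexpected character '", ch, "' in SMILES '", s, "'")
  }
  if (length(rings)) stop("unmatched ring-closure label in SMILES '", s, "'")
  atoms <- data.frame(element = el, aromatic = arom, charge = chg,
                      stringsAsFactors = FALSE)
  bonds <- as.data.frame(bnd)
  names(bonds) <- c("a1", "a2", "order")
  atoms$nH <- .implicit_h(atoms, bonds, exH)
  mol <- structure(list(smiles = can, atoms = atoms, bonds = bonds),
                   class = "tp_mol")
  assign(ck, mol, envir = .tp_cache)
  mol
}

.implicit_h <- function(atoms, bonds, exH) {
  n <- nrow(atoms)
  bsum <- numeric(n); deg <- integer(n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    o <- if (bonds$order[k] == 1.5) 1 else bonds$order[k]
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + o
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + o
    deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
    deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
  }
  vapply(seq_len(n), function(i) {
    if (!is.na(exH[i])) return(exH[i])            # bracket atom: explicit
    e <- atoms$element[i]
    v <- .organic_valence[[e]]
    if (is.null(v)) return(0L)
    b <- bsum[i]
    if (atoms$aromatic[i]) {
      # delocalization increment: aromatic C always; aromatic N only when
      # pyridine-like (two ring connections)
      if (e == "C" || (e == "N" && deg[i] == 2L)) b <- b + 1
    }
    vv <- v[v >= b]
    if (!length(vv)) return(0L)
    as.integer(vv[1] - b)
  }, integer(1))
}

#' @export
print.tp_mol <- function(x, ...) {
  cat("<molecule> ", x$smiles, " (", nrow(x$atoms), " heavy atoms)\n", sep = "")
  invisible(x)
}

#' Molecular formula of a parsed molecule
#'
#' @param mol A `tp_mol`.
#' @return A `mol_formula` including implicit hydrogens.
#' @export
mol_formula <- function(mol) {
  stopifnot(inherits(mol, "tp_mol"))
  tab <- table(mol$atoms$element)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  hs <- sum(mol$atoms$nH)
  if (hs > 0) counts["H"] <- .cnt0(counts, "H") + hs
  mf_new(counts)
}

.cnt0 <- function(x, e) if (e %in% names(x)) x[[e]] else 0L

n_heavy <- function(mol) nrow(mol$atoms)

# ---- circular fingerprints -------------------------------------------------

.str_hash <- function(x) {
  # deterministic 31-bit polynomial string hash
  vapply(x, function(s) {
    h <- 17
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Circular (Morgan-style) fingerprint
#'
#' Hashed circular substructure fingerprint: atom environments of radius
#' 0..`radius` are hashed into `nbits` bits. Used with the Tanimoto
#' coefficient for structure similarity.
#'
#' @param mol A `tp_mol` or SMILES string.
#' @param radius Neighborhood radius (default 2).
#' @param nbits Number of bits (default 2048).
#' @return Sorted integer vector of set bit positions (0-based).
#' @export
morgan_bits <- function(mol, radius = 2L, nbits = 2048L) {
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  key <- paste0("fp:", radius, ":", nbits, ":", mol$smiles)
  if (exists(key, envir = .tp_cache)) return(get(key, envir = .tp_cache))
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  nbr <- vector("list", n)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    nbr[[bd$a1[k]]] <- rbind(nbr[[bd$a1[k]]], c(bd$a2[k], bd$order[k]))
    nbr[[bd$a2[k]]] <- rbind(nbr[[bd$a2[k]]], c(bd$a1[k], bd$order[k]))
  }
  inv <- paste0(at$element, "|", at$aromatic, "|", at$nH, "|", at$charge, "|",
                vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1)))
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      if (is.null(nbr[[i]])) return(paste0("T", inv[i]))
      env <- sort(paste0(nbr[[i]][, 2], ">", inv[nbr[[i]][, 1]]))
      paste0(inv[i], "(", paste(env, collapse = ";"), ")")
    }, character(1))
    all_inv <- c(all_inv, inv)
  }
  bits <- sort(unique(floor(.str_hash(unique(all_inv)) %% nbits)))
  assign(key, bits, envir = .tp_cache)
  bits
}

#' Structure similarity (Tanimoto)
#'
#' Tanimoto coefficient between the circular fingerprints of two
#' structures. Symmetric, bounded in \[0, 1\], and 1 for structures with
#' identical fingerprints.
#'
#' @param a,b `tp_mol`, `structure_record`, or SMILES.
#' @param radius,nbits Fingerprint parameters.
#' @return Similarity in \[0, 1\].
#' @export
structure_similarity <- function(a, b, radius = 2L, nbits = 2048L) {
  fa <- morgan_bits(.as_mol(a), radius, nbits)
  fb <- morgan_bits(.as_mol(b), radius, nbits)
  if (length(fa) == 0L && length(fb) == 0L) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

.as_mol <- function(x) {
  if (inherits(x, "tp_mol")) x
  else if (inherits(x, "structure_record")) x$mol
  else if (is.character(x)) mol_from_smiles(x)
  else stop("cannot interpret object as a molecule")
}

# ---- log P -----------------------------------------------------------------

#' Predict log P
#'
#' Atom-contribution octanol/water partition coefficient (OpenBabel's
#' Wildman-Crippen style model). Deterministic; cached per canonical
#' SMILES. Used by the elution-order filter under the reversed-phase
#' assumption that higher log P elutes later.
#'
#' @param smiles SMILES string(s) or structure record(s).
#' @return Numeric log P value(s); `NA` with a warning on prediction
#'   failure.
#' @export
predict_logp <- function(smiles) {
  if (inherits(smiles, "structure_record")) smiles <- smiles$smiles
  keys <- paste0("logp:", smiles)
  out <- rep(NA_real_, length(smiles))
  hit <- vapply(keys, function(k) exists(k, envir = .tp_cache), logical(1))
  out[hit] <- vapply(keys[hit], function(k) get(k, envir = .tp_cache), numeric(1))
  todo <- which(!hit)
  if (length(todo)) {
    res <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[todo]))
      suppressWarnings(ChemmineR::cid(sdf) <- paste0("m", seq_along(todo)))
      p <- ChemmineR::propOB(sdf)
      as.numeric(p$logP)
    }, error = function(e) {
      warning("log P prediction failed: ", conditionMessage(e))
      rep(NA_real_, length(todo))
    })
    if (length(res) != length(todo)) res <- rep(NA_real_, length(todo))
    out[todo] <- res
    for (i in seq_along(todo))
      assign(keys[todo[i]], out[todo[i]], envir = .tp_cache)
  }
  out
}

# ---- structure records -----------------------------------------------------

#' Create a structure record
#'
#' Bundles an identifier, SMILES, parsed graph, formula, monoisotopic mass
#' and (lazily computed) log P.
#'
#' @param id Identifier.
#' @param smiles SMILES string.
#' @param logp Optional precomputed log P (computed on demand otherwise).
#' @return A `structure_record`.
#' @export
structure_record <- function(id, smiles, logp = NULL) {
  mol <- mol_from_smiles(smiles)
  f <- mol_formula(mol)
  structure(list(id = id, smiles = mol$smiles, mol = mol, formula = f,
                 monoisotopic_mass = mf_mass(f), logp = logp),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure> ", x$id, ": ", x$smiles, " [", mf_render(x$formula),
      ", ", round(x$monoisotopic_mass, 4), " Da]\n", sep = "")
  invisible(x)
}

record_logp <- function(rec) {
  if (is.null(rec$logp)) predict_logp(rec$smiles) else rec$logp
}
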