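# MS2 annotation: background removal, formula enumeration for precursors,
# subformula assignment of fragment peaks, in-silico bond-disconnection
# fragmentation of candidate structures, and the derived annotation scores.

#' Remove background peaks using flanking spectra
#'
#' Removes peaks whose intensity is at most `background_factor` times the
#' intensity of a matching peak (within `frag_tol_mda`) in any flanking
#' spectrum acquired off the chromatographic peak, then applies a relative
#' intensity floor. With no flanking spectra only the floor applies. The
#' operation never adds peaks and is idempotent for a fixed flanking set.
#'
#' @param target `ms2_spectrum` to clean.
#' @param flanking List of off-peak `ms2_spectrum` objects.
#' @param config Configuration (uses `background_factor`, `frag_tol_mda`,
#'   `rel_int_floor`).
#' @return Cleaned `ms2_spectrum`.
#' @export
remove_background <- function(target, flanking = list(), config = default_config()) {
  pk <- target$peaks
  if (nrow(pk)) {
    tol <- config$frag_tol_mda / 1000
    keep <- rep(TRUE, nrow(pk))
    for (fl in flanking) {
      if (!nrow(fl$peaks)) next
      for (i in seq_len(nrow(pk))) {
        if (!keep[i]) next
        d <- abs(fl$peaks[, 1] - pk[i, 1])
        if (any(d <= tol) && pk[i, 2] <= config$background_factor *
              max(fl$peaks[d <= tol, 2]))
          keep[i] <- FALSE
      }
    }
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk)) pk <- pk[pk[, 2] >= config$rel_int_floor * max(pk[, 2]), ,
                           drop = FALSE]
  }
  ms2_spectrum(target$feature_group_id, target$precursor_mz, pk)
}

#' Enumerate candidate molecular formulas for an m/z
#'
#' All formulas over `alphabet` within the element-count `bounds` whose
#' `[M+H]+` m/z lies within `tol_mda` of the query, filtered to
#' ring-double-bond equivalents >= 0 and integer RDBE (even-electron
#' neutral molecules), sorted by absolute mass error.
#'
#' @param mz Query m/z (protonated ion).
#' @param tol_mda Tolerance in mDa.
#' @param alphabet Elements considered (subset of C,H,N,O,S,F).
#' @param bounds Named integer vector of maximum counts.
#' @return Data frame: `formula`, `error_mda`, `rdbe`.
#' @export
enumerate_formulas <- function(mz, tol_mda = 5,
                               alphabet = default_alphabet(),
                               bounds = c(C = 20, H = 40, N = 5, O = 8,
                                          S = 2, F = 6)) {
  stopifnot(mz > 0)
  iso <- .tp_isotopes
  target <- mz - .tp_proton_mass
  tol <- tol_mda / 1000
  b <- function(e) if (e %in% alphabet && e %in% names(bounds)) bounds[[e]] else 0L
  mh <- iso$H$mass
  out <- list()
  for (c_ in 0:b("C")) {
    mc <- c_ * iso$C$mass
    if (mc > target + tol) break
    for (n_ in 0:b("N")) {
      mn <- mc + n_ * iso$N$mass
      if (mn > target + tol) break
      for (o_ in 0:b("O")) {
        mo <- mn + o_ * iso$O$mass
        if (mo > target + tol) break
        for (s_ in 0:b("S")) {
          ms <- mo + s_ * iso$S$mass
          if (ms > target + tol) break
          for (f_ in 0:b("F")) {
            mf <- ms + f_ * iso$F$mass
            if (mf > target + tol) break
            # solve the hydrogen count directly
            h0 <- round((target - mf) / mh)
            for (h_ in (h0 - 1):(h0 + 1)) {
              if (h_ < 0 || h_ > b("H")) next
              m <- mf + h_ * mh
              err <- m - target
              if (abs(err) > tol) next
              if (c_ + h_ + n_ + o_ + s_ + f_ == 0) next
              rdbe <- c_ + 1 - (h_ + f_) / 2 + n_ / 2
              if (rdbe < 0 || abs(rdbe - round(rdbe)) > 1e-9) next
              cnt <- c(C = c_, H = h_, N = n_, O = o_, S = s_, F = f_)
              cnt <- cnt[cnt > 0]
              out[[length(out) + 1L]] <- data.frame(
                formula = mf_render(mf_new(cnt)),
                error_mda = err * 1000, rdbe = rdbe)
            }
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(formula = character(0), error_mda = numeric(0),
                      rdbe = numeric(0)))
  res <- unique(do.call(rbind, out))
  res[order(abs(res$error_mda)), , drop = FALSE]
}

# all element-wise subformulas of f (including f, excluding empty),
# as neutral masses
.subformula_masses <- function(f) {
  els <- names(f)
  grids <- lapply(els, function(e) 0:f[[e]])
  grid <- do.call(expand.grid, grids)
  names(grid) <- els
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  masses <- as.matrix(grid) %*%
    vapply(els, function(e) .tp_isotopes[[e]]$mass, numeric(1))
  lab <- apply(grid, 1, function(r) {
    cnt <- r[r > 0]
    mf_render(mf_new(setNames(as.integer(cnt), names(cnt))))
  })
  data.frame(formula = lab, mass = as.numeric(masses), stringsAsFactors = FALSE)
}

#' Assign fragment subformulas to MS2 peaks
#'
#' Every peak is assigned the subformula of the precursor formula (as the
#' protonated fragment) with the smallest absolute mass error within
#' tolerance, or left unassigned. Peaks heavier than the protonated
#' precursor stay unassigned.
#'
#' @param spectrum `ms2_spectrum`.
#' @param precursor_formula `mol_formula` or string.
#' @param config Configuration (uses `frag_tol_mda`).
#' @return An `annotated_spectrum`: list with the spectrum, the
#'   per-peak `assignments` data frame (`mz`, `intensity`, `formula`,
#'   `error_mda`) and `explained_intensity_fraction`.
#' @export
annotate_fragments <- function(spectrum, precursor_formula,
                               config = default_config()) {
  f <- mf_parse(precursor_formula, names(.tp_isotopes))
  sub <- .subformula_masses(f)
  tol <- config$frag_tol_mda / 1000
  pk <- spectrum$peaks
  res <- data.frame(mz = numeric(0), intensity = numeric(0),
                    formula = character(0), error_mda = numeric(0))
  if (nrow(pk)) {
    res <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i) {
      mzi <- pk[i, 1]
      err <- mzi - (sub$mass + .tp_proton_mass)
      j <- which.min(abs(err))
      if (length(j) && abs(err[j]) <= tol &&
          mzi <= mf_mass(f) + .tp_proton_mass + tol)
        data.frame(mz = mzi, intensity = pk[i, 2], formula = sub$formula[j],
                   error_mda = err[j] * 1000)
      else
        data.frame(mz = mzi, intensity = pk[i, 2], formula = NA_character_,
                   error_mda = NA_real_)
    }))
  }
  expl <- if (nrow(res) && sum(res$intensity) > 0)
    sum(res$intensity[!is.na(res$formula)]) / sum(res$intensity) else NA_real_
  structure(list(spectrum = spectrum, precursor_formula = mf_render(f),
                 assignments = res, explained_intensity_fraction = expl),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("<annotated MS2> ", x$spectrum$feature_group_id, " (",
      x$precursor_formula, "), explained intensity ",
      round(100 * x$explained_intensity_fraction, 1), "%\n", sep = "")
  invisible(x)
}

# ---- in-silico fragmentation ----------------------------------------------

.mol_bridges <- function(mol) {
  # bridge = bond whose removal disconnects the graph
  n <- nrow(mol$atoms); bd <- mol$bonds
  if (!nrow(bd)) return(logical(0))
  vapply(seq_len(nrow(bd)), function(k) {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (j in seq_len(nrow(bd))) {
      if (j == k) next
      adj[[bd$a1[j]]] <- c(adj[[bd$a1[j]]], bd$a2[j])
      adj[[bd$a2[j]]] <- c(adj[[bd$a2[j]]], bd$a1[j])
    }
    seen <- rep(FALSE, n); stack <- bd$a1[k]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    !seen[bd$a2[k]]
  }, logical(1))
}

.components_after_cut <- function(mol, cut) {
  # union-find over the bonds that survive the cut
  n <- nrow(mol$atoms); bd <- mol$bonds
  par <- seq_len(n)
  find <- function(v) {
    while (par[v] != v) { par[v] <<- par[par[v]]; v <- par[v] }
    as.integer(v)
  }
  keep <- setdiff(seq_len(nrow(bd)), cut)
  for (j in keep) {
    r1 <- find(bd$a1[j]); r2 <- find(bd$a2[j])
    if (r1 != r2) par[r2] <- r1
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

.atoms_formula <- function(mol, atoms) {
  cnt <- table(mol$atoms$element[atoms])
  counts <- setNames(as.integer(cnt), names(cnt))
  hs <- sum(mol$atoms$nH[atoms])
  if (hs > 0) counts["H"] <- .cnt0(counts, "H") + hs
  mf_new(counts)
}

#' In-silico fragmentation by bond disconnection
#'
#' Generates the unique fragment set obtained by breaking up to `depth`
#' acyclic bonds (ring bonds are broken pairwise, which counts as one
#' disconnection step). Each fragment keeps its atoms' hydrogens; hydrogen
#' rearrangement is handled at match time as a +/- 1 H tolerance. Fragment
#' counts are monotone nondecreasing in `depth`; `depth = 0` yields only
#' the intact molecule.
#'
#' @param s `structure_record`, `tp_mol` or SMILES.
#' @param depth Maximum number of disconnection steps.
#' @param max_cut_sets Budget on enumerated cut sets; exceeding it returns
#'   the fragments found so far flagged with attribute `partial = TRUE`.
#' @return Data frame: `formula`, `mass` (neutral), `mz` (`[frag+H]+`),
#'   `n_cuts`.
#' @export
fragment_structure <- function(s, depth = 2L, max_cut_sets = 20000L) {
  mol <- .as_mol(s)
  key <- paste0("frag:", depth, ":", mol$smiles)
  if (exists(key, envir = .tp_cache)) return(get(key, envir = .tp_cache))
  stopifnot(depth >= 0)
  nb <- nrow(mol$bonds)
  bridges <- which(.mol_bridges(mol))
  ringb <- setdiff(seq_len(nb), bridges)
  cuts <- list(integer(0))
  if (depth >= 1) {
    # one disconnection step = one acyclic bond or one pair of ring bonds;
    # at most one ring opening per cut set
    bsteps <- lapply(bridges, identity)
    rsteps <- if (length(ringb) >= 2) utils::combn(ringb, 2, simplify = FALSE)
      else list()
    for (nb in seq_len(depth)) {
      if (nb > length(bridges)) break
      cuts <- c(cuts, if (length(bridges) == 1L) list(bridges)
                else utils::combn(bridges, nb, simplify = FALSE))
    }
    if (length(rsteps)) {
      cuts <- c(cuts, rsteps)
      if (depth >= 2) for (rp in rsteps)
        cuts <- c(cuts, lapply(bridges, function(b) c(rp, b)))
    }
    cuts <- cuts[vapply(cuts, function(cut) {
      nb <- sum(cut %in% bridges)
      nb + (length(cut) > nb) <= depth
    }, logical(1))]
  }
  partial <- length(cuts) > max_cut_sets
  if (partial) cuts <- cuts[seq_len(max_cut_sets)]
  # precomputed per-atom element index for fast component formulas
  els <- sort(unique(c(mol$atoms$element, "H")))
  eidx <- match(mol$atoms$element, els)
  emass <- vapply(els, function(e) .tp_isotopes[[e]]$mass, numeric(1))
  seen <- new.env()
  rows <- list()
  for (cut in cuts) {
    comps <- .components_after_cut(mol, cut)
    if (length(cut) && length(comps) < 2) next
    for (atoms in comps) {
      cnt <- tabulate(eidx[atoms], nbins = length(els))
      names(cnt) <- els
      cnt[["H"]] <- cnt[["H"]] + sum(mol$atoms$nH[atoms])
      lab <- paste(els[cnt > 0], cnt[cnt > 0], collapse = "", sep = "")
      if (exists(lab, seen)) next
      assign(lab, TRUE, seen)
      m <- sum(cnt * emass)
      rows[[length(rows) + 1L]] <- data.frame(
        formula = mf_render(mf_new(cnt[cnt > 0])), mass = m,
        mz = m + .tp_proton_mass, n_cuts = length(cut))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mass), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "partial") <- partial
  assign(key, out, envir = .tp_cache)
  out
}

#' Compound annotation score
#'
#' Intensity-weighted fraction of MS2 peaks explained by the in-silico
#' fragment masses of a candidate structure (within `frag_tol_mda`,
#' allowing +/- `frag_h_tolerance` hydrogen rearrangements). Returns `NA`
#' (a distinguished "absent" result, not zero) when no spectrum is
#' available.
#'
#' @param spectrum `ms2_spectrum` (cleaned), or `NULL`.
#' @param s Candidate structure.
#' @param config Configuration.
#' @return Score in \[0, 1\], or `NA_real_` when no MS2 is available.
#' @export
compound_annotation_score <- function(spectrum, s, config = default_config()) {
  if (is.null(spectrum) || !nrow(spectrum$peaks)) return(NA_real_)
  fr <- fragment_structure(s, config$frag_depth)
  tol <- config$frag_tol_mda / 1000
  hshift <- (-config$frag_h_tolerance):config$frag_h_tolerance *
    .tp_isotopes$H$mass
  cand_mz <- as.numeric(outer(fr$mz, hshift, `+`))
  pk <- spectrum$peaks
  matched <- vapply(pk[, 1], function(m) any(abs(cand_mz - m) <= tol),
                    logical(1))
  sum(pk[matched, 2]) / sum(pk[, 2])
}

#' Annotation similarity
#'
#' Jaccard index of assigned fragment-formula sets from two annotated
#' spectra (or explicit formula character vectors). Symmetric, in
#' \[0, 1\]; empty-vs-empty is defined as 0.
#'
#' @param a,b `annotated_spectrum` objects or character vectors of
#'   fragment formulas.
#' @return Jaccard similarity.
#' @export
ann_similarity <- function(a, b) {
  fa <- .frag_set(a); fb <- .frag_set(b)
  if (!length(fa) && !length(fb)) return(0)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

.frag_set <- function(x) {
  if (inherits(x, "annotated_spectrum"))
    unique(x$assignments$formula[!is.na(x$assignments$formula)])
  else unique(as.character(x))
}
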