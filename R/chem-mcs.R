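# Maximum-common-substructure size and the parent "fit" metric built on it.

.mol_graph_codes <- function(a, b) {
  els <- sort(unique(c(a$atoms$element, b$atoms$element)))
  enc <- function(mol) {
    n <- nrow(mol$atoms)
    adj <- matrix(0L, n, n)
    bd <- mol$bonds
    if (nrow(bd)) for (k in seq_len(nrow(bd))) {
      code <- if (bd$order[k] == 1.5) 4L else as.integer(bd$order[k])
      adj[bd$a1[k], bd$a2[k]] <- code
      adj[bd$a2[k], bd$a1[k]] <- code
    }
    list(el = match(mol$atoms$element, els) - 1L, adj = adj)
  }
  list(a = enc(a), b = enc(b), n_elements = length(els))
}

#' Maximum common substructure size
#'
#' Size (heavy-atom count) of the largest connected, element- and
#' bond-order-matched common induced subgraph of two molecules. The search
#' is exact within the time budget; on timeout the best size found so far
#' is returned, flagged as a conservative lower bound.
#'
#' @param a,b Molecules (`tp_mol`, `structure_record`, or SMILES).
#' @param time_budget_s Wall-clock budget per pair in seconds (default 2).
#' @return List with `size` (integer) and `timed_out` (logical).
#' @export
mcs_size <- function(a, b, time_budget_s = 2) {
  a <- .as_mol(a); b <- .as_mol(b)
  key <- paste0("mcs:", time_budget_s, ":", a$smiles, "~", b$smiles)
  if (exists(key, envir = .tp_cache)) return(get(key, envir = .tp_cache))
  g <- .mol_graph_codes(a, b)
  res <- .mcs_size_cpp(g$a$el, g$a$adj, g$b$el, g$b$adj, g$n_elements,
                       time_budget_s)
  res$size <- as.integer(res$size)
  assign(key, res, envir = .tp_cache)
  assign(paste0("mcs:", time_budget_s, ":", b$smiles, "~", a$smiles), res,
         envir = .tp_cache)
  res
}

#' Structural fit of a candidate in a parent
#'
#' MCS-based fit: `|MCS| / n_heavy(candidate)` and `|MCS| /
#' n_heavy(parent)` are computed and combined (maximum by default). A
#' candidate that is a substructure of the parent (or vice versa) has fit 1.
#'
#' @param candidate,parent Molecules (`tp_mol`, `structure_record`, or
#'   SMILES).
#' @param direction `"max"` (default), `"candidate"` (fit of the candidate
#'   in the parent) or `"parent"`.
#' @param time_budget_s MCS time budget per pair (seconds).
#' @return Numeric fit in \[0, 1\], with attributes `fit_candidate`,
#'   `fit_parent` and `timed_out`.
#' @export
structure_fit <- function(candidate, parent, direction = c("max", "candidate", "parent"),
                          time_budget_s = 2) {
  direction <- match.arg(direction)
  cm <- .as_mol(candidate); pm <- .as_mol(parent)
  r <- mcs_size(cm, pm, time_budget_s)
  fc <- r$size / n_heavy(cm)
  fp <- r$size / n_heavy(pm)
  val <- switch(direction, max = max(fc, fp), candidate = fc, parent = fp)
  structure(val, fit_candidate = fc, fit_parent = fp, timed_out = r$timed_out)
}
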