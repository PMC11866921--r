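# Molecular formula algebra, monoisotopic masses, adduct m/z and isotope
# patterns. Formulas are named integer vectors (element -> count) of class
# "mol_formula", rendered in Hill order.

# Embedded isotope table (IUPAC-CIAAW 2021 atomic masses and representative
# isotopic abundances). `offset` is the nominal mass shift relative to the
# most abundant (monoisotopic) isotope.
.tp_isotopes <- local({
  iso <- list(
    H  = list(mass = 1.0078250319,  offsets = c(0, 1),      ab = c(0.999885, 0.000115)),
    C  = list(mass = 12.0,          offsets = c(0, 1),      ab = c(0.9893, 0.0107)),
    N  = list(mass = 14.0030740052, offsets = c(0, 1),      ab = c(0.99636, 0.00364)),
    O  = list(mass = 15.9949146221, offsets = c(0, 1, 2),   ab = c(0.99757, 0.00038, 0.00205)),
    F  = list(mass = 18.9984031627, offsets = 0,            ab = 1),
    P  = list(mass = 30.9737615120, offsets = 0,            ab = 1),
    S  = list(mass = 31.9720706912, offsets = c(0, 1, 2, 4), ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
    Cl = list(mass = 34.9688527100, offsets = c(0, 2),      ab = c(0.7576, 0.2424)),
    Br = list(mass = 78.9183376000, offsets = c(0, 2),      ab = c(0.5069, 0.4931)),
    Si = list(mass = 27.9769265327, offsets = c(0, 1, 2),   ab = c(0.92223, 0.04685, 0.03092))
  )
  iso
})

.tp_proton_mass <- 1.007276

#' Default element alphabet
#'
#' Elements allowed in formulas by default: the parents studied plus common
#' oxidation chemistry (C, H, N, O, S, F). Chlorine, bromine, silicon and
#' phosphorus are known to the mass table but excluded from the default
#' alphabet; they are used by the candidate element filter.
#'
#' @return Character vector of element symbols.
#' @export
default_alphabet <- function() c("C", "H", "N", "O", "S", "F")

#' Parse a molecular formula string
#'
#' Parses an element-count string such as `"C10H11N3O3S"` into a
#' `mol_formula` object. Elements must belong to `alphabet` and counts must
#' be positive.
#'
#' @param text Formula string (Hill order not required).
#' @param alphabet Allowed element symbols.
#' @return A `mol_formula`: named integer vector of element counts.
#' @examples
#' mf_parse("C6H7N")
#' @export
mf_parse <- function(text, alphabet = default_alphabet()) {
  if (inherits(text, "mol_formula")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    stop("malformed formula string: '", text, "'")
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.tp_isotopes))
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    if (!el %in% alphabet)
      stop("element '", el, "' not in the configured alphabet (",
           paste(alphabet, collapse = ","), ")")
    if (n <= 0L) stop("zero count for element '", el, "' in formula '", text, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  mf_new(counts)
}

mf_new <- function(counts) {
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("empty formula (no atoms)")
  storage.mode(counts) <- "integer"
  structure(counts[.hill_order(names(counts))], class = "mol_formula")
}

.hill_order <- function(els) {
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    c("C", intersect("H", els), rest)
  } else sort(els)
}

#' Render a formula in Hill order
#'
#' @param f A `mol_formula`.
#' @return Canonical formula string (carbon first, then hydrogen, then
#'   remaining elements alphabetically; counts of one omitted).
#' @export
mf_render <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  paste0(names(f), ifelse(f > 1L, f, ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula>", mf_render(x), " (", format(mf_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' @export
format.mol_formula <- function(x, ...) mf_render(x)

#' Formula arithmetic
#'
#' Element-wise sum and difference of molecular formulas, used to apply
#' transformation deltas (e.g. metoprolol + H2O2, flecainide - C2HF3) when
#' building formula suspects with metabolic logic.
#'
#' @param a,b `mol_formula` objects (or strings parsed with the extended
#'   mass-table alphabet).
#' @return A `mol_formula`. `mf_subtract()` fails, naming the deficient
#'   element, when a count would become negative, and rejects an empty
#'   result.
#' @export
mf_add <- function(a, b) {
  a <- mf_parse(a, names(.tp_isotopes)); b <- mf_parse(b, names(.tp_isotopes))
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) .cnt(a, e) + .cnt(b, e), integer(1))
  names(out) <- els
  mf_new(out)
}

#' @rdname mf_add
#' @export
mf_subtract <- function(a, b) {
  a <- mf_parse(a, names(.tp_isotopes)); b <- mf_parse(b, names(.tp_isotopes))
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) .cnt(a, e) - .cnt(b, e), integer(1))
  names(out) <- els
  bad <- names(out)[out < 0L]
  if (length(bad))
    stop("subtraction leaves negative count for element(s): ",
         paste(bad, collapse = ", "))
  if (all(out == 0L)) stop("subtraction yields an empty formula")
  mf_new(out)
}

.cnt <- function(f, e) if (e %in% names(f)) f[[e]] else 0L

#' Monoisotopic mass
#'
#' Sum of most-abundant-isotope masses over the formula, from the embedded
#' atomic-mass table.
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass in Da.
#' @export
mf_mass <- function(f) {
  f <- mf_parse(f, names(.tp_isotopes))
  sum(vapply(names(f), function(e) .tp_isotopes[[e]]$mass, numeric(1)) * as.numeric(f))
}

#' Adduct m/z
#'
#' m/z of an ionized molecule. Only `[M+H]+` is enabled by default,
#' matching positive-mode electrospray; the adduct table can be extended
#' through the `adducts` argument.
#'
#' @param mass Neutral monoisotopic mass (Da) or a `mol_formula`.
#' @param adduct Adduct label, e.g. `"[M+H]+"`.
#' @param adducts Named list of functions mass -> m/z.
#' @return m/z value.
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+",
                      adducts = list("[M+H]+" = function(m) m + .tp_proton_mass)) {
  if (inherits(mass, "mol_formula") || is.character(mass)) mass <- mf_mass(mass)
  if (!adduct %in% names(adducts))
    stop("unsupported adduct label '", adduct, "'")
  adducts[[adduct]](mass)
}

#' Ring-and-double-bond equivalents
#'
#' RDBE = C + Si + 1 - (H + F + Cl + Br)/2 + (N + P)/2 for neutral,
#' even-electron molecules.
#'
#' @param f A `mol_formula` or string.
#' @return RDBE (may be half-integral for odd-electron compositions).
#' @export
mf_rdbe <- function(f) {
  f <- mf_parse(f, names(.tp_isotopes))
  .cnt(f, "C") + .cnt(f, "Si") + 1 -
    (.cnt(f, "H") + .cnt(f, "F") + .cnt(f, "Cl") + .cnt(f, "Br")) / 2 +
    (.cnt(f, "N") + .cnt(f, "P")) / 2
}

#' Isotope pattern by nominal mass offset
#'
#' Convolves the per-element isotope distributions of a formula and
#' aggregates isotopologues with equal nominal mass, giving the relative
#' abundance of the M+1, M+2, ... clusters with the monoisotopic peak
#' normalized to 1. The M+2 cluster of a sulfur-containing analyte is what
#' makes saturation-free quantitation on the M+2 channel possible.
#'
#' @param f A `mol_formula` or string.
#' @param max_offset Largest nominal offset to report (>= 2).
#' @return An `iso_pattern`: data frame with columns `offset` and
#'   `abundance` (fraction of the monoisotopic peak).
#' @export
isotope_pattern <- function(f, max_offset = 4L) {
  f <- mf_parse(f, names(.tp_isotopes))
  stopifnot(max_offset >= 2L)
  n <- max_offset + 1L
  dist <- c(1, rep(0, max_offset))          # probability by offset, truncated
  for (e in names(f)) {
    iso <- .tp_isotopes[[e]]
    at <- rep(0, n)
    at[iso$offsets[iso$offsets <= max_offset] + 1L] <-
      iso$ab[iso$offsets <= max_offset]
    # per-element distribution for f[[e]] atoms: repeated self-convolution
    eld <- c(1, rep(0, max_offset))
    pw <- at
    k <- f[[e]]
    while (k > 0L) {
      if (k %% 2L == 1L) eld <- .conv_trunc(eld, pw, n)
      k <- k %/% 2L
      if (k > 0L) pw <- .conv_trunc(pw, pw, n)
    }
    dist <- .conv_trunc(dist, eld, n)
  }
  ab <- dist / dist[1L]
  structure(data.frame(offset = 0:max_offset, abundance = ab),
            class = c("iso_pattern", "data.frame"))
}

.conv_trunc <- function(a, b, n) {
  out <- rep(0, n)
  for (i in seq_len(n)) {
    j <- seq_len(n - i + 1L)
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

#' @export
print.iso_pattern <- function(x, ...) {
  cat("<isotope pattern>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
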