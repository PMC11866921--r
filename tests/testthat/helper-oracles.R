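# Independent brute-force oracles used across the suite.

# Isotope pattern by exhaustive multinomial enumeration of isotopologue
# compositions per element (no polynomial convolution).
iso_pattern_oracle <- function(formula, max_offset = 4L) {
  f <- mf_parse(formula, c("C", "H", "N", "O", "S", "F", "Cl", "Br", "Si", "P"))
  iso <- tpscreen:::.tp_isotopes
  # per element: probability of each total nominal offset for n atoms
  comp_dist <- function(offsets, probs, n) {
    k <- length(offsets)
    out <- new.env()
    rec <- function(i, left, off, p) {
      if (i == k) {
        off <- off + left * offsets[k]
        p <- p * probs[k]^left
        key <- as.character(off)
        assign(key, p + (if (exists(key, out)) get(key, out) else 0), out)
        return()
      }
      for (m in 0:left)
        rec(i + 1L, left - m, off + m * offsets[i],
            p * choose(left, m) * probs[i]^m)  # binomial chain = multinomial
    }
    rec(1L, n, 0L, 1)
    offs <- as.integer(ls(out))
    ab <- vapply(ls(out), function(k) get(k, out), numeric(1))
    data.frame(offset = offs, p = unname(ab))
  }
  total <- data.frame(offset = 0L, p = 1)
  for (e in names(f)) {
    d <- comp_dist(iso[[e]]$offsets, iso[[e]]$ab, f[[e]])
    grid <- expand.grid(i = seq_len(nrow(total)), j = seq_len(nrow(d)))
    comb <- data.frame(offset = total$offset[grid$i] + d$offset[grid$j],
                       p = total$p[grid$i] * d$p[grid$j])
    total <- stats::aggregate(p ~ offset, comb, sum)
    total <- total[total$offset <= max_offset + 4L, ]
  }
  total <- total[order(total$offset), ]
  total <- total[total$offset <= max_offset, ]
  data.frame(offset = total$offset, abundance = total$p / total$p[1])
}

# OLS via explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- X %*% beta
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

# Maximum common connected induced subgraph by exhaustive enumeration:
# all connected atom subsets of the first molecule, all injective
# element/bond-order-preserving embeddings into the second.
mcs_oracle <- function(a, b) {
  a <- tpscreen:::.as_mol(a); b <- tpscreen:::.as_mol(b)
  adj <- function(mol) {
    n <- nrow(mol$atoms)
    m <- matrix(0, n, n)
    bd <- mol$bonds
    if (nrow(bd)) for (k in seq_len(nrow(bd))) {
      m[bd$a1[k], bd$a2[k]] <- bd$order[k]
      m[bd$a2[k], bd$a1[k]] <- bd$order[k]
    }
    m
  }
  A <- adj(a); B <- adj(b)
  ea <- a$atoms$element; eb <- b$atoms$element
  na <- length(ea); nb <- length(eb)
  stopifnot(na <= 12, nb <= 14)
  connected <- function(S, M) {
    if (length(S) <= 1) return(TRUE)
    seen <- S[1]; grow <- TRUE
    while (grow) {
      grow <- FALSE
      for (v in setdiff(S, seen))
        if (any(M[v, seen] != 0)) { seen <- c(seen, v); grow <- TRUE }
    }
    length(seen) == length(S)
  }
  embeds <- function(S) {
    # injective map S -> atoms of b preserving element and induced bonds
    rec <- function(i, used, map) {
      if (i > length(S)) return(TRUE)
      u <- S[i]
      for (v in setdiff(which(eb == ea[u]), used)) {
        ok <- TRUE
        for (j in seq_len(i - 1L))
          if (A[u, S[j]] != B[v, map[j]]) { ok <- FALSE; break }
        if (ok && rec(i + 1L, c(used, v), c(map, v))) return(TRUE)
      }
      FALSE
    }
    rec(1L, integer(0), integer(0))
  }
  for (k in seq(min(na, nb), 1L)) {
    subsets <- utils::combn(na, k, simplify = FALSE)
    for (S in subsets)
      if (connected(S, A) && embeds(S)) return(k)
  }
  0L
}

# Exhaustive nested-loop formula enumeration (including the H loop).
enumerate_formulas_oracle <- function(mz, tol_mda, bounds) {
  iso <- tpscreen:::.tp_isotopes
  target <- mz - 1.007276
  res <- character(0)
  for (c_ in 0:bounds[["C"]]) for (n_ in 0:bounds[["N"]])
    for (o_ in 0:bounds[["O"]]) for (s_ in 0:bounds[["S"]])
      for (f_ in 0:bounds[["F"]]) for (h_ in 0:bounds[["H"]]) {
        if (c_ + n_ + o_ + s_ + f_ + h_ == 0) next
        m <- c_ * iso$C$mass + h_ * iso$H$mass + n_ * iso$N$mass +
          o_ * iso$O$mass + s_ * iso$S$mass + f_ * iso$F$mass
        if (abs(m - target) > tol_mda / 1000) next
        rdbe <- c_ + 1 - (h_ + f_) / 2 + n_ / 2
        if (rdbe < 0 || abs(rdbe - round(rdbe)) > 1e-9) next
        cnt <- c(C = c_, H = h_, N = n_, O = o_, S = s_, F = f_)
        cnt <- cnt[cnt > 0]
        res <- c(res, mf_render(tpscreen:::mf_new(cnt)))
      }
  sort(unique(res))
}

# Pooled two-sample t-test, textbook formulas.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
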