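# Reference RNA free-energy backend: a Zuker-style minimum-free-energy
# dynamic program over nested secondary structures, scored with a simplified
# nearest-neighbour model (stacking bonuses for Watson-Crick and GU stacks,
# logarithmic hairpin-loop penalty, affine bulge/internal penalties, affine
# multiloop). The same score tables drive an exhaustive structure enumerator
# used as an independent oracle for short sequences, and a register-scan
# hybridization energy for sRNA-seed / mRNA-site duplexes.
#
# Units are kcal/mol-like; the tables are simplified constants, not measured
# Turner parameters, so absolute values are comparable only within a backend.

# --- energy parameters ------------------------------------------------------

.pair_strength <- c(AU = 2, UA = 2, CG = 3, GC = 3, GU = 1, UG = 1)

pair_code <- function(a, b) paste0(a, b)

pairable <- function(a, b) pair_code(a, b) %in% names(.pair_strength)

# stacking energy of pair (i,j) on adjacent pair (i+1,j-1)
stack_energy <- function(a_i, b_j, a_k, b_l) {
  s1 <- .pair_strength[pair_code(a_i, b_j)]
  s2 <- .pair_strength[pair_code(a_k, b_l)]
  unname(-(0.5 + 0.4 * (s1 + s2)))
}

hairpin_energy <- function(l) {
  ifelse(l < 3, Inf, 4.5 + 1.1 * log(l / 3))
}

bulge_energy <- function(l) 3.6 + 0.4 * l

internal_energy <- function(l1, l2) 1.8 + 0.4 * (l1 + l2) + 0.3 * abs(l1 - l2)

ML_CLOSE <- 3.4   # multiloop closing penalty
ML_BRANCH <- 0.4  # per branch (closing pair included)
ML_UNPAIRED <- 0.1
MAXLOOP <- 30     # largest bulge/internal loop considered by the DP
DUPLEX_INIT <- 4.1
DUPLEX_BULGE <- 3.8

# --- MFE dynamic program ----------------------------------------------------

#' Minimum free energy of a sequence under the reference backend
#'
#' Zuker-style recursion with paired (V), multiloop-segment (M) and external
#' (W) matrices over the simplified nearest-neighbour score. The open chain
#' scores 0, so the return value is always <= 0.
#'
#' @param sequence RNA string (T accepted).
#' @return list with `energy` (kcal/mol) and `structure` (dot-bracket of one
#'   optimal structure; traceback by recomputation).
#' @export
fold_mfe_reference <- function(sequence) {
  s <- seq_chars(normalize_rna(sequence, allow_n = FALSE))
  n <- length(s)
  if (n < 5) return(list(energy = 0, structure = strrep(".", n)))
  P <- matrix(pairable(s[rep(seq_len(n), n)], s[rep(seq_len(n), each = n)]),
              nrow = n)
  V <- matrix(Inf, n, n)
  M <- matrix(Inf, n, n)
  for (d in 1:(n - 1)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      # V(i,j): energy of the best structure on [i,j] closed by pair (i,j)
      if (d >= 4 && P[i, j]) {
        best <- hairpin_energy(d - 1)
        if (P[i + 1, j - 1] && is.finite(V[i + 1, j - 1])) {
          best <- min(best, V[i + 1, j - 1] +
                        stack_energy(s[i], s[j], s[i + 1], s[j - 1]))
        }
        # bulges and internal loops
        kmax <- min(j - 5, i + 1 + MAXLOOP)
        for (k in if (kmax >= i + 1) (i + 1):kmax else integer(0)) {
          l1 <- k - i - 1
          lmin <- max(k + 4, j - 1 - (MAXLOOP - l1))
          if (lmin > j - 1) next
          for (l in lmin:(j - 1)) {
            l2 <- j - l - 1
            if (l1 + l2 == 0) next
            if (!is.finite(V[k, l])) next
            pen <- if (l1 == 0 || l2 == 0) bulge_energy(l1 + l2)
                   else internal_energy(l1, l2)
            cand <- V[k, l] + pen
            if (cand < best) best <- cand
          }
        }
        # multiloop: closing pair + >= 2 branches inside
        if (d >= 10) {
          for (m in (i + 1):(j - 2)) {
            if (is.finite(M[i + 1, m]) && is.finite(M[m + 1, j - 1])) {
              cand <- ML_CLOSE + ML_BRANCH + M[i + 1, m] + M[m + 1, j - 1]
              if (cand < best) best <- cand
            }
          }
        }
        V[i, j] <- best
      }
      # M(i,j): best multiloop segment on [i,j] containing >= 1 branch
      mbest <- Inf
      if (is.finite(V[i, j])) mbest <- V[i, j] + ML_BRANCH
      if (d >= 1) {
        if (is.finite(M[i + 1, j])) mbest <- min(mbest, M[i + 1, j] + ML_UNPAIRED)
        if (is.finite(M[i, j - 1])) mbest <- min(mbest, M[i, j - 1] + ML_UNPAIRED)
        if (d >= 2) {
          for (m in i:(j - 1)) {
            if (is.finite(M[i, m]) && is.finite(M[m + 1, j])) {
              cand <- M[i, m] + M[m + 1, j]
              if (cand < mbest) mbest <- cand
            }
          }
        }
      }
      M[i, j] <- mbest
    }
  }
  W <- numeric(n + 1) # W[j+1]: best energy of prefix 1..j
  for (j in seq_len(n)) {
    best <- W[j]
    for (i in seq_len(max(0, j - 4))) {
      if (is.finite(V[i, j])) best <- min(best, W[i] + V[i, j])
    }
    W[j + 1] <- best
  }
  list(energy = W[n + 1], structure = tb_structure(n, W, V, M, s))
}

# traceback by recomputation (kept separate from the fill for clarity)
tb_structure <- function(n, W, V, M, s) {
  db <- rep(".", n)
  eps <- 1e-9
  trace_V <- function(i, j) {
    db[i] <<- "("; db[j] <<- ")"
    e <- V[i, j]
    d <- j - i
    if (abs(e - hairpin_energy(d - 1)) < eps) return(invisible())
    if (pairable(s[i + 1], s[j - 1]) && is.finite(V[i + 1, j - 1]) &&
        abs(e - (V[i + 1, j - 1] + stack_energy(s[i], s[j], s[i + 1], s[j - 1]))) < eps) {
      return(trace_V(i + 1, j - 1))
    }
    kmax <- min(j - 5, i + 1 + MAXLOOP)
    for (k in if (kmax >= i + 1) (i + 1):kmax else integer(0)) {
      l1 <- k - i - 1
      lmin <- max(k + 4, j - 1 - (MAXLOOP - l1))
      if (lmin > j - 1) next
      for (l in lmin:(j - 1)) {
        l2 <- j - l - 1
        if (l1 + l2 == 0 || !is.finite(V[k, l])) next
        pen <- if (l1 == 0 || l2 == 0) bulge_energy(l1 + l2)
               else internal_energy(l1, l2)
        if (abs(e - (V[k, l] + pen)) < eps) return(trace_V(k, l))
      }
    }
    if (d >= 10) {
      for (m in (i + 1):(j - 2)) {
        if (is.finite(M[i + 1, m]) && is.finite(M[m + 1, j - 1]) &&
            abs(e - (ML_CLOSE + ML_BRANCH + M[i + 1, m] + M[m + 1, j - 1])) < eps) {
          trace_M(i + 1, m); trace_M(m + 1, j - 1); return(invisible())
        }
      }
    }
    invisible()
  }
  trace_M <- function(i, j) {
    e <- M[i, j]
    if (is.finite(V[i, j]) && abs(e - (V[i, j] + ML_BRANCH)) < 1e-9) {
      return(trace_V(i, j))
    }
    if (j > i) {
      if (is.finite(M[i + 1, j]) && abs(e - (M[i + 1, j] + ML_UNPAIRED)) < 1e-9) {
        return(trace_M(i + 1, j))
      }
      if (is.finite(M[i, j - 1]) && abs(e - (M[i, j - 1] + ML_UNPAIRED)) < 1e-9) {
        return(trace_M(i, j - 1))
      }
      if (j - i >= 2) {
        for (m in i:(j - 1)) {
          if (is.finite(M[i, m]) && is.finite(M[m + 1, j]) &&
              abs(e - (M[i, m] + M[m + 1, j])) < 1e-9) {
            trace_M(i, m); trace_M(m + 1, j); return(invisible())
          }
        }
      }
    }
    invisible()
  }
  trace_W <- function(j) {
    while (j >= 5) {
      if (abs(W[j + 1] - W[j]) < 1e-9) { j <- j - 1; next }
      hit <- FALSE
      for (i in seq_len(j - 4)) {
        if (is.finite(V[i, j]) && abs(W[j + 1] - (W[i] + V[i, j])) < 1e-9) {
          trace_V(i, j); j <- i - 1; hit <- TRUE; break
        }
      }
      if (!hit) j <- j - 1
    }
  }
  trace_W(n)
  paste0(db, collapse = "")
}

# --- loop-decomposition scorer + exhaustive enumeration (oracle) ------------

#' Free energy of a given structure under the reference score tables
#'
#' Decomposes a dot-bracket structure into its loops (hairpins, stacks,
#' bulges, internal loops, multiloops) and sums their energies. Shares only
#' the primitive score tables with the dynamic program, so agreement between
#' [fold_mfe_reference()] and minimization over [enumerate_structures()] is a
#' genuine two-route check.
#'
#' @param sequence RNA string.
#' @param db dot-bracket structure of the same length.
#' @return energy in kcal/mol (0 for the open chain).
#' @export
structure_energy <- function(sequence, db) {
  s <- seq_chars(normalize_rna(sequence, allow_n = FALSE))
  pt <- pair_table(db)
  n <- length(s)
  if (length(pt) != n) stop("structure/sequence length mismatch")
  score_pair <- function(i, j) {
    if (!pairable(s[i], s[j])) stop("structure pairs non-pairable bases ", i, "-", j)
    # children: maximal pairs strictly inside (i,j)
    kids <- list()
    k <- i + 1
    unpaired <- 0L
    while (k < j) {
      if (pt[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(kids) == 0) {
      return(hairpin_energy(j - i - 1))
    }
    if (length(kids) == 1) {
      kk <- kids[[1]]
      l1 <- kk[1] - i - 1
      l2 <- j - kk[2] - 1
      e_kid <- score_pair(kk[1], kk[2])
      if (l1 == 0 && l2 == 0) {
        return(e_kid + stack_energy(s[i], s[j], s[kk[1]], s[kk[2]]))
      }
      if (l1 == 0 || l2 == 0) return(e_kid + bulge_energy(l1 + l2))
      return(e_kid + internal_energy(l1, l2))
    }
    e <- ML_CLOSE + ML_BRANCH * (length(kids) + 1) + ML_UNPAIRED * unpaired
    for (kk in kids) e <- e + score_pair(kk[1], kk[2])
    e
  }
  total <- 0
  k <- 1
  while (k <= n) {
    if (pt[k] > k) {
      total <- total + score_pair(k, pt[k])
      k <- pt[k] + 1
    } else {
      k <- k + 1
    }
  }
  total
}

#' Enumerate all nested secondary structures of a short sequence
#'
#' All structures with minimum hairpin-loop length 3 whose pairs are
#' Watson-Crick or GU. Exponential; intended as an oracle for sequences of
#' up to ~14 nt.
#'
#' @param sequence RNA string.
#' @return character vector of dot-bracket strings (includes the open chain).
#' @export
enumerate_structures <- function(sequence) {
  s <- seq_chars(normalize_rna(sequence, allow_n = FALSE))
  n <- length(s)
  if (n > 18) stop("enumeration is an oracle for short sequences (<= 18 nt)")
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i + 1 < 5) {
      return(list(strrep(".", max(0, j - i + 1))))
    }
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(gen(i + 1, j), function(x) paste0(".", x))
    for (k in (i + 4):j) {
      if (pairable(s[i], s[k])) {
        inner <- gen(i + 1, k - 1)
        rest <- gen(k + 1, j)
        for (a in inner) for (b in rest) {
          out[[length(out) + 1L]] <- paste0("(", a, ")", b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  unlist(gen(1, n))
}

# --- duplex (hybridization) energy ------------------------------------------

#' Hybridization free energy of two short RNAs under the reference backend
#'
#' Scans all antiparallel alignment registers between `seq_a` and `seq_b`,
#' allowing at most one single-nucleotide bulge on either strand, and scores
#' each register as a duplex-initiation penalty plus stacking energies over
#' runs of consecutive complementary (WC or GU) pairs. Returns the minimum,
#' capped at 0 (no stable duplex).
#'
#' @param seq_a,seq_b RNA strings, both 5'->3'.
#' @return duplex energy in kcal/mol (<= 0).
#' @export
duplex_energy_reference <- function(seq_a, seq_b) {
  a <- seq_chars(normalize_rna(seq_a, allow_n = FALSE))
  b <- rev(seq_chars(normalize_rna(seq_b, allow_n = FALSE)))
  na <- length(a); nb <- length(b)
  score_map <- function(map) {
    # map: integer vector along a; map[i] = index into b or NA
    idx <- which(!is.na(map))
    idx <- idx[pairable(a[idx], b[map[idx]])]
    if (length(idx) < 2) return(Inf)
    e <- DUPLEX_INIT
    any_stack <- FALSE
    for (t in seq_len(length(idx) - 1)) {
      i1 <- idx[t]; i2 <- idx[t + 1]
      if (i2 == i1 + 1 && map[i2] == map[i1] + 1) {
        e <- e + stack_energy(a[i1], b[map[i1]], a[i2], b[map[i2]])
        any_stack <- TRUE
      }
    }
    if (!any_stack) return(Inf)
    e
  }
  best <- 0
  for (o in (-(nb - 1)):(na - 1)) {
    base_map <- seq_len(na) - o
    base_map[base_map < 1 | base_map > nb] <- NA
    best <- min(best, score_map(base_map))
    # one bulge on strand a (skip one a base) or strand b (skip one b base)
    for (t in seq_len(na)) {
      m1 <- base_map
      keep <- seq_len(na) > t & !is.na(m1)
      m1[keep] <- m1[keep] - 1
      m1[t] <- NA
      m1[m1 < 1 | m1 > nb] <- NA
      e1 <- score_map(m1)
      if (is.finite(e1)) best <- min(best, e1 + DUPLEX_BULGE)
      m2 <- base_map
      sel <- seq_len(na) >= t & !is.na(m2)
      m2[sel] <- m2[sel] + 1
      m2[m2 < 1 | m2 > nb] <- NA
      e2 <- score_map(m2)
      if (is.finite(e2)) best <- min(best, e2 + DUPLEX_BULGE)
    }
  }
  min(best, 0)
}

# --- backend objects ---------------------------------------------------------

#' Construct an energy backend
#'
#' `"reference"` is the self-contained nearest-neighbour backend implemented
#' in this package; `"vienna"` shells out to the RNAfold/RNAcofold
#' executables if they are on the PATH. Numerical equality across backends is
#' not expected: each backend's numbers are only comparable to its own. Both
#' backends memoize by sequence.
#'
#' @param name "reference" or "vienna".
#' @return object of class `energy_backend` with functions `fold_mfe(seq)`
#'   and `duplex_energy(seq_a, seq_b)`.
#' @export
energy_backend <- function(name = c("reference", "vienna")) {
  name <- match.arg(name)
  cache <- new.env(parent = emptyenv())
  memo <- function(key, fn) {
    if (is.null(cache[[key]])) cache[[key]] <- fn()
    cache[[key]]
  }
  if (name == "reference") {
    fold <- function(sequence) {
      memo(paste0("f:", sequence),
           function() fold_mfe_reference(sequence)$energy)
    }
    duplex <- function(seq_a, seq_b) {
      memo(paste0("d:", seq_a, "&", seq_b),
           function() duplex_energy_reference(seq_a, seq_b))
    }
  } else {
    if (Sys.which("RNAfold") == "" || Sys.which("RNAcofold") == "") {
      stop("vienna backend requires RNAfold and RNAcofold on the PATH")
    }
    fold <- function(sequence) {
      memo(paste0("f:", sequence), function() {
        out <- system2("RNAfold", c("--noPS"), stdout = TRUE,
                       input = normalize_rna(sequence, allow_n = FALSE))
        parse_vienna_energy(out)
      })
    }
    duplex <- function(seq_a, seq_b) {
      memo(paste0("d:", seq_a, "&", seq_b), function() {
        inp <- paste0(normalize_rna(seq_a, FALSE), "&",
                      normalize_rna(seq_b, FALSE))
        out <- system2("RNAcofold", c("--noPS"), stdout = TRUE, input = inp)
        parse_vienna_energy(out)
      })
    }
  }
  structure(list(name = name, fold_mfe = fold, duplex_energy = duplex),
            class = "energy_backend")
}

parse_vienna_energy <- function(lines) {
  m <- regmatches(lines, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", lines))
  m <- m[lengths(m) > 0 | nzchar(m)]
  m <- m[nzchar(m)]
  if (length(m) == 0) stop("could not parse ViennaRNA output")
  as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
}

#' Stem-loop self-folding free energy of a variant
#'
#' Applies the variant's substitutions to the full sequence, extracts the
#' annotated stem-loop subsequence and folds it. A variant whose stem-loop is
#' less stable than the wild type (ddG_fold > 0) is flagged "loose".
#'
#' @param reference a `reference_srna`.
#' @param v an `srna_variant` or canonical key.
#' @param stem_loop name of an annotated stem-loop.
#' @param backend an `energy_backend`.
#' @return list with `dG` (variant), `dG_wt`, `ddG`, `loose`.
#' @export
fold_energy <- function(reference, v, stem_loop, backend = energy_backend()) {
  sl <- reference$stem_loops[[stem_loop]]
  if (is.null(sl)) stop("unknown stem-loop: ", stem_loop)
  full <- apply_substitutions(v, reference)
  sub <- substr(full, sl$start, sl$end)
  wt_sub <- substr(reference$sequence, sl$start, sl$end)
  dG <- backend$fold_mfe(sub)
  dG_wt <- backend$fold_mfe(wt_sub)
  list(dG = dG, dG_wt = dG_wt, ddG = dG - dG_wt, loose = (dG - dG_wt) > 0)
}

#' Seed-target hybridization free energy of a variant
#'
#' Duplex energy between the variant's seed region and the target's mRNA
#' site. By default the variant's mutations must intersect the seed interval
#' (the quantity is only informative there); pass `seed_only = FALSE` to
#' compute it for any variant.
#'
#' @param reference a `reference_srna`.
#' @param v an `srna_variant` or canonical key.
#' @param target a target name or target spec from the reference.
#' @param backend an `energy_backend`.
#' @param seed_only require mutations (if any) to touch the seed interval.
#' @return list with `dG`, `dG_wt`, `ddG`.
#' @export
binding_energy <- function(reference, v, target, backend = energy_backend(),
                           seed_only = FALSE) {
  if (is.character(target)) target <- reference$targets[[target]]
  if (is.null(target)) stop("unknown target")
  if (is.character(v)) v <- parse_variant_key(v, reference)
  iv <- target$srna_seed_interval
  if (seed_only && length(v$pos) > 0 &&
      !any(v$pos >= iv[1] & v$pos <= iv[2])) {
    stop("variant has no mutation in the seed interval ", iv[1], "-", iv[2],
         "; use seed_only = FALSE to compute anyway")
  }
  full <- apply_substitutions(v, reference)
  seed <- substr(full, iv[1], iv[2])
  wt_seed <- substr(reference$sequence, iv[1], iv[2])
  site <- substr(target$mrna_site, target$mrna_site_interval[1],
                 target$mrna_site_interval[2])
  dG <- backend$duplex_energy(seed, site)
  dG_wt <- backend$duplex_energy(wt_seed, site)
  list(dG = dG, dG_wt = dG_wt, ddG = dG - dG_wt)
}
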