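#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. All sequences are handled internally in
#' RNA space; DNA input (amplicon reads) is accepted transparently.
#'
#' @param x character scalar over A/C/G/T/U/N (case-insensitive).
#' @param allow_n whether ambiguous N bases are permitted.
#' @return normalized character scalar.
#' @export
normalize_rna <- function(x, allow_n = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  ok <- c(RNA_BASES, if (allow_n) "N")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), ok)
  if (length(bad) > 0) {
    stop("non-nucleotide characters in sequence: ", paste(bad, collapse = ", "))
  }
  x
}

seq_chars <- function(x) strsplit(x, "")[[1]]

#' Pair table from a dot-bracket string
#'
#' @param structure dot-bracket string using '(', ')' and '.' (or any
#'   unpaired marker).
#' @return integer vector p of length nchar(structure); p[i] is the partner
#'   of position i, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- seq_chars(structure)
  n <- length(ch)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced structure: ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced structure: unmatched '(' at position ",
         paste(stack, collapse = ","))
  }
  p
}

is_wc_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC")
}

is_gu_pair <- function(a, b) {
  paste0(a, b) %in% c("GU", "UG")
}

can_pair_bases <- function(a, b) is_wc_pair(a, b) | is_gu_pair(a, b)

check_interval <- function(iv, L, what) {
  if (length(iv) != 2L || anyNA(iv) || iv[1] < 1 || iv[2] > L || iv[1] > iv[2]) {
    stop(what, ": interval [", iv[1], ",", iv[2], "] out of bounds for length ", L)
  }
  invisible(iv)
}

#' Construct a reference sRNA object
#'
#' The coordinate frame for the whole analysis: wild-type sequence, solved
#' secondary structure (dot-bracket), stem-loop and region annotations, and
#' the target specifications. Coordinates are 1-based inclusive throughout.
#'
#' @param name identifier.
#' @param sequence RNA string over A/C/G/U (T accepted, converted).
#' @param structure dot-bracket string of the same length.
#' @param stem_loops named list; each element a list with `start` and `end`.
#' @param regions named list of length-2 integer intervals.
#' @param targets list of target specs, each a list with `name`,
#'   `mode` ("repressed" or "activated"), `mrna_site` (RNA string),
#'   `srna_seed_interval`, `mrna_site_interval`.
#' @return object of class `reference_srna` with a derived pair table and
#'   per-stem-loop paired-position lists.
#' @export
reference_srna <- function(name, sequence, structure, stem_loops = list(),
                           regions = list(), targets = list()) {
  sequence <- normalize_rna(sequence, allow_n = FALSE)
  L <- nchar(sequence)
  if (nchar(structure) != L) {
    stop("structure length (", nchar(structure),
         ") does not match sequence length (", L, ")")
  }
  pt <- pair_table(structure)
  bases <- seq_chars(sequence)
  # annotated pairs must be at least pairable (WC or GU) in the wild type
  for (i in which(pt > 0 & pt > seq_len(L))) {
    if (!can_pair_bases(bases[i], bases[pt[i]])) {
      stop("structure pairs positions ", i, " and ", pt[i],
           " but bases ", bases[i], "-", bases[pt[i]], " cannot pair")
    }
  }
  sls <- lapply(seq_along(stem_loops), function(k) {
    sl <- stem_loops[[k]]
    nm <- if (!is.null(sl$name)) sl$name else names(stem_loops)[k]
    iv <- c(as.integer(sl$start), as.integer(sl$end))
    check_interval(iv, L, paste0("stem_loop ", nm))
    inside <- seq.int(iv[1], iv[2])
    paired <- inside[pt[inside] > 0]
    if (any(!(pt[paired] %in% inside))) {
      stop("stem_loop ", nm, ": structure pairs cross the annotated interval")
    }
    up <- paired[paired < pt[paired]]
    list(name = nm, start = iv[1], end = iv[2],
         pairs = cbind(i = up, j = pt[up]))
  })
  names(sls) <- vapply(sls, `[[`, "", "name")
  regs <- lapply(regions, function(iv) {
    iv <- as.integer(iv)
    check_interval(iv, L, "region")
    iv
  })
  tgts <- lapply(targets, function(tg) {
    stopifnot(!is.null(tg$name), !is.null(tg$mode))
    if (!tg$mode %in% c("repressed", "activated")) {
      stop("target ", tg$name, ": mode must be 'repressed' or 'activated'")
    }
    site <- normalize_rna(tg$mrna_site, allow_n = FALSE)
    seed_iv <- as.integer(tg$srna_seed_interval)
    site_iv <- as.integer(tg$mrna_site_interval)
    check_interval(seed_iv, L, paste0("target ", tg$name, " seed"))
    check_interval(site_iv, nchar(site), paste0("target ", tg$name, " site"))
    list(name = tg$name, mode = tg$mode, mrna_site = site,
         srna_seed_interval = seed_iv, mrna_site_interval = site_iv)
  })
  names(tgts) <- vapply(tgts, `[[`, "", "name")
  structure(
    list(name = name, sequence = sequence, structure = structure,
         length = L, pairs = pt, bases = bases,
         stem_loops = sls, regions = regs, targets = tgts),
    class = "reference_srna"
  )
}

#' @export
print.reference_srna <- function(x, ...) {
  cat("<reference_srna> ", x$name, " (", x$length, " nt)\n", sep = "")
  cat(" ", x$sequence, "\n ", x$structure, "\n", sep = "")
  for (sl in x$stem_loops) {
    cat("  stem-loop ", sl$name, ": ", sl$start, "-", sl$end,
        " (", nrow(sl$pairs), " pairs)\n", sep = "")
  }
  for (tg in x$targets) {
    cat("  target ", tg$name, " [", tg$mode, "], seed ",
        tg$srna_seed_interval[1], "-", tg$srna_seed_interval[2], "\n", sep = "")
  }
  invisible(x)
}

#' Load a reference sRNA configuration from YAML
#'
#' Reads a structured config (sequence, dot-bracket structure, stem-loops,
#' regions, targets) and returns a validated [reference_srna()]. All
#' invariants are checked at load time; inconsistent configs fail loudly.
#'
#' @param path path to a YAML config file.
#' @return a `reference_srna` object.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  req <- c("name", "sequence", "structure")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0) {
    stop("config missing required fields: ", paste(miss, collapse = ", "))
  }
  reference_srna(
    name = cfg$name,
    sequence = cfg$sequence,
    structure = cfg$structure,
    stem_loops = if (is.null(cfg$stem_loops)) list() else cfg$stem_loops,
    regions = if (is.null(cfg$regions)) list() else cfg$regions,
    targets = if (is.null(cfg$targets)) list() else cfg$targets
  )
}

#' Path to a packaged reference configuration
#'
#' The packaged configs are designed synthetic stand-ins for the two
#' E. coli sRNAs analysed in the source experiments: they reproduce the
#' published coordinate anchors (length, three stem-loops 5' to 3', seed
#' placement, poly-U tail) with a designed sequence whose annotated pairs
#' are Watson-Crick consistent, but they are not the published sequences.
#'
#' @param which "ryhb" or "dsra".
#' @return file path inside the installed package.
#' @export
packaged_reference <- function(which = c("ryhb", "dsra")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_synthetic.yaml"),
              package = "qsortseq", mustWork = TRUE)
}

#' Which stem-loop contains a position
#'
#' @param reference a `reference_srna`.
#' @param pos 1-based position vector.
#' @return character vector of stem-loop names (NA where unannotated).
#' @export
stem_loop_of <- function(reference, pos) {
  out <- rep(NA_character_, length(pos))
  for (sl in reference$stem_loops) {
    hit <- pos >= sl$start & pos <= sl$end
    out[hit] <- sl$name
  }
  out
}
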