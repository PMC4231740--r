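# Variant representation: a set of substitutions against the wild type.
# The canonical key is ref-base + position + alt-base joined by ";" in
# position order (e.g. "A30G;U55A"); the wild type has the reserved key "WT".

WT_KEY <- "WT"
EMPTY_VECTOR_KEY <- "NOSRNA" # empty-vector (no-sRNA) control row

#' Construct a variant from a substitution set
#'
#' @param positions 1-based positions (strictly increasing after sorting,
#'   duplicates are an error).
#' @param alt alternative bases (RNA alphabet) at those positions.
#' @param reference a `reference_srna`; supplies and checks the ref bases.
#' @return object of class `srna_variant` with fields `pos`, `ref`, `alt`,
#'   `key`. An empty substitution set is the wild type.
#' @export
variant <- function(positions, alt, reference) {
  positions <- as.integer(positions)
  if (length(positions) != length(alt)) stop("positions/alt length mismatch")
  if (anyDuplicated(positions)) stop("duplicate substitution positions")
  o <- order(positions)
  positions <- positions[o]
  alt <- toupper(chartr("Tt", "UU", as.character(alt)))[o]
  if (length(positions) > 0) {
    if (any(positions < 1 | positions > reference$length)) {
      stop("substitution position out of range 1..", reference$length)
    }
    if (!all(alt %in% RNA_BASES)) stop("alt bases must be A/C/G/U")
    ref <- reference$bases[positions]
    if (any(alt == ref)) {
      stop("alt base equals the wild-type base at position ",
           paste(positions[alt == ref], collapse = ","))
    }
  } else {
    ref <- character(0)
  }
  structure(
    list(pos = positions, ref = ref, alt = alt,
         key = variant_key(positions, ref, alt)),
    class = "srna_variant"
  )
}

variant_key <- function(pos, ref, alt) {
  if (length(pos) == 0) return(WT_KEY)
  paste0(ref, pos, alt, collapse = ";")
}

#' Parse a canonical variant key back into a variant
#'
#' @param key canonical key such as `"A30G;U55A"`, or `"WT"`.
#' @param reference a `reference_srna`.
#' @return an `srna_variant`.
#' @export
parse_variant_key <- function(key, reference) {
  if (identical(key, WT_KEY) || !nzchar(key)) {
    return(variant(integer(0), character(0), reference))
  }
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([ACGU])([0-9]+)([ACGU])$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed variant key: ", key)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  ref <- vapply(m, `[[`, "", 2L)
  alt <- vapply(m, `[[`, "", 4L)
  v <- variant(pos, alt, reference)
  if (!identical(v$ref, ref)) {
    stop("key ", key, " ref bases disagree with the reference sequence")
  }
  v
}

#' Apply a variant's substitutions to the wild-type sequence
#'
#' @param v an `srna_variant` (or canonical key string).
#' @param reference a `reference_srna`.
#' @return the mutated RNA sequence (character scalar).
#' @export
apply_substitutions <- function(v, reference) {
  if (is.character(v)) v <- parse_variant_key(v, reference)
  b <- reference$bases
  b[v$pos] <- v$alt
  paste0(b, collapse = "")
}

#' @export
print.srna_variant <- function(x, ...) {
  cat("<srna_variant> ", x$key, "\n", sep = "")
  invisible(x)
}

#' Call a variant from a full-length amplicon read
#'
#' Reads are assumed pre-oriented, full-length amplicons; comparison is
#' equal-length Hamming only. Any length difference is rejected as a
#' putative indel (indels are out of scope), and reads containing N are
#' rejected as ambiguous.
#'
#' @param read DNA or RNA string (T and U equivalent).
#' @param reference a `reference_srna`.
#' @return an `srna_variant` on success, or a `variant_rejection` (list with
#'   `reason` in `c("length_mismatch", "ambiguous_base")`).
#' @export
call_variant <- function(read, reference) {
  read <- normalize_rna(read, allow_n = TRUE)
  if (nchar(read) != reference$length) {
    return(structure(list(reason = "length_mismatch"),
                     class = "variant_rejection"))
  }
  rb <- seq_chars(read)
  if (any(rb == "N")) {
    return(structure(list(reason = "ambiguous_base"),
                     class = "variant_rejection"))
  }
  mism <- which(rb != reference$bases)
  variant(mism, rb[mism], reference)
}

#' @export
print.variant_rejection <- function(x, ...) {
  cat("<variant_rejection> ", x$reason, "\n", sep = "")
  invisible(x)
}

is_rejection <- function(x) inherits(x, "variant_rejection")

# number of substitutions in a canonical key (WT -> 0)
key_n_mutations <- function(key) {
  ifelse(key %in% c(WT_KEY, EMPTY_VECTOR_KEY), 0L,
         lengths(strsplit(key, ";", fixed = TRUE)))
}

# positions encoded in canonical keys, as a list of integer vectors
key_positions <- function(key) {
  lapply(strsplit(ifelse(key %in% c(WT_KEY, EMPTY_VECTOR_KEY), "", key),
                  ";", fixed = TRUE),
         function(parts) {
           parts <- parts[nzchar(parts)]
           as.integer(sub("^[ACGU]([0-9]+)[ACGU]$", "\\1", parts))
         })
}
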