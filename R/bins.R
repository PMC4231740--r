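# Sorting gates and the per-variant bin-count table: the raw observable of
# a sort-seq experiment.

#' Construct sorting gates
#'
#' @param boundaries strictly increasing vector of log10-fluorescence gate
#'   boundaries, length n_bins + 1.
#' @return object of class `sort_gates`.
#' @export
sort_gates <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 3) stop("need at least 2 bins (3 boundaries)")
  if (anyNA(boundaries) || any(!is.finite(boundaries))) {
    stop("gate boundaries must be finite")
  }
  if (any(diff(boundaries) <= 0)) stop("gate boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, n_bins = length(boundaries) - 1L),
            class = "sort_gates")
}

#' @export
print.sort_gates <- function(x, ...) {
  cat("<sort_gates> ", x$n_bins, " bins: ",
      paste(signif(x$boundaries, 4), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Construct a bin-count table
#'
#' @param counts data.frame with column `variant_key` and one integer count
#'   column per bin (`bin1`..`binK`).
#' @param gates a `sort_gates` with matching bin number.
#' @param cells_sorted integer vector: cells deposited per bin by the sorter.
#' @param reads_sequenced integer vector: total reads sequenced per bin
#'   (defaults to the column sums).
#' @param rejected integer vector: reads rejected per bin (indels/ambiguous).
#' @return object of class `bin_count_table`.
#' @export
bin_count_table <- function(counts, gates, cells_sorted = NULL,
                            reads_sequenced = NULL, rejected = NULL) {
  stopifnot(is.data.frame(counts), "variant_key" %in% names(counts))
  k <- gates$n_bins
  bin_cols <- paste0("bin", seq_len(k))
  if (!all(bin_cols %in% names(counts))) {
    stop("counts must have columns ", paste(bin_cols, collapse = ", "))
  }
  if (anyDuplicated(counts$variant_key)) stop("duplicate variant keys")
  cm <- as.matrix(counts[bin_cols])
  if (any(cm < 0) || any(cm != round(cm))) stop("counts must be non-negative integers")
  colsums <- colSums(cm)
  if (is.null(reads_sequenced)) reads_sequenced <- colsums
  if (is.null(cells_sorted)) cells_sorted <- reads_sequenced
  if (is.null(rejected)) rejected <- integer(k)
  stopifnot(length(reads_sequenced) == k, length(cells_sorted) == k,
            length(rejected) == k)
  structure(
    list(counts = counts[c("variant_key", bin_cols)],
         gates = gates, n_bins = k,
         cells_sorted = as.numeric(cells_sorted),
         reads_sequenced = as.numeric(reads_sequenced),
         rejected = as.integer(rejected)),
    class = "bin_count_table"
  )
}

#' @export
print.bin_count_table <- function(x, ...) {
  cat("<bin_count_table> ", nrow(x$counts), " variants x ", x$n_bins,
      " bins; ", sum(x$rejected), " rejected reads\n", sep = "")
  invisible(x)
}

count_matrix <- function(tbl) {
  m <- as.matrix(tbl$counts[paste0("bin", seq_len(tbl$n_bins))])
  rownames(m) <- tbl$counts$variant_key
  m
}

#' Tabulate per-bin reads into a bin-count table
#'
#' Each read is called against the reference (equal-length Hamming match);
#' rejected reads (putative indels, ambiguous bases) are tallied separately
#' per bin and never enter the counts.
#'
#' @param reads_per_bin list (ordered by gate) of character vectors of reads,
#'   or paths to plain one-read-per-line text / FASTA files.
#' @param reference a `reference_srna`.
#' @param gates a `sort_gates`; length must match the number of bins.
#' @param cells_sorted optional per-bin sorted-cell totals for the metadata.
#' @return a `bin_count_table`.
#' @export
tabulate_bins <- function(reads_per_bin, reference, gates, cells_sorted = NULL) {
  k <- length(reads_per_bin)
  if (k != gates$n_bins) stop("number of read collections must match gates")
  reads_per_bin <- lapply(reads_per_bin, function(x) {
    if (length(x) == 1 && is.character(x) && file.exists(x)) read_reads_file(x) else x
  })
  if (sum(lengths(reads_per_bin)) == 0) stop("no reads in any bin")
  keys_per_bin <- vector("list", k)
  rejected <- integer(k)
  for (b in seq_len(k)) {
    calls <- lapply(reads_per_bin[[b]], call_variant, reference = reference)
    rej <- vapply(calls, is_rejection, TRUE)
    rejected[b] <- sum(rej)
    keys_per_bin[[b]] <- vapply(calls[!rej], `[[`, "", "key")
  }
  all_keys <- sort(unique(unlist(keys_per_bin)))
  cm <- vapply(keys_per_bin, function(ks) {
    tab <- table(factor(ks, levels = all_keys))
    as.integer(tab)
  }, integer(length(all_keys)))
  cm <- matrix(cm, nrow = length(all_keys),
               dimnames = list(NULL, paste0("bin", seq_len(k))))
  counts <- data.frame(variant_key = all_keys, cm,
                       stringsAsFactors = FALSE, check.names = FALSE)
  bin_count_table(counts, gates, cells_sorted = cells_sorted,
                  rejected = rejected)
}

read_reads_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    # FASTA: concatenate sequence lines per record
    idx <- cumsum(startsWith(lines, ">"))
    seqs <- split(lines[!startsWith(lines, ">")], idx[!startsWith(lines, ">")])
    vapply(seqs, paste0, "", collapse = "")
  } else {
    lines[nzchar(lines)]
  }
}

#' Write / read a bin-count table as TSV plus a YAML metadata sidecar
#'
#' The TSV holds `variant_key` and the per-bin counts; the sidecar
#' (`<path>.meta.yaml`) holds gates, per-bin sorted-cell and sequenced-read
#' totals, and the rejected tallies. The round trip is lossless.
#'
#' @param tbl a `bin_count_table`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(tbl, path) {
  utils::write.table(tbl$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    gates = as.numeric(tbl$gates$boundaries),
    cells_sorted = as.numeric(tbl$cells_sorted),
    reads_sequenced = as.numeric(tbl$reads_sequenced),
    rejected = as.integer(tbl$rejected)
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  counts <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
  counts$variant_key <- as.character(counts$variant_key)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  bin_count_table(counts, sort_gates(meta$gates),
                  cells_sorted = meta$cells_sorted,
                  reads_sequenced = meta$reads_sequenced,
                  rejected = meta$rejected)
}
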