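test_that("packaged reference configs load with consistent annotations", {
  expect_s3_class(ryhb, "reference_srna")
  expect_equal(ryhb$length, 94L)
  expect_equal(names(ryhb$stem_loops), c("SL1", "SL2", "SL3"))
  # SL2 ends at position 55: its most downstream base
  expect_equal(ryhb$stem_loops$SL2$end, 55L)
  expect_equal(ryhb$bases[55], "U")
  # region split covers the full molecule
  expect_equal(ryhb$regions$end, c(68L, 94L))
  expect_equal(ryhb$regions$start[1], 1L)
  # every annotated pair is WC or GU consistent (checked at load, spot-check)
  pt <- ryhb$pairs
  paired <- which(pt > seq_along(pt))
  expect_true(length(paired) > 15)
  for (i in paired) {
    expect_true(paste0(ryhb$bases[i], ryhb$bases[pt[i]]) %in%
                  c("AU", "UA", "CG", "GC", "GU", "UG"))
  }
  # seeds are perfectly complementary to their annotated sites
  for (tg in ryhb$targets) {
    seed <- substr(ryhb$sequence, tg$srna_seed_interval[1],
                   tg$srna_seed_interval[2])
    site <- substr(tg$mrna_site, tg$mrna_site_interval[1],
                   tg$mrna_site_interval[2])
    rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(site, "")[[1]]),
                                       collapse = ""))
    expect_equal(seed, rc)
  }
  dsra <- load_reference(packaged_reference("dsra"))
  expect_equal(length(dsra$stem_loops), 3L)
})

test_that("inconsistent configs fail loudly", {
  expect_error(
    reference_srna("bad", "ACGUACGUA", "...((...", list()),
    "length"
  )
  expect_error(
    reference_srna("bad", "ACGUACGU", "((......", list()),
    "unbalanced"
  )
  expect_error(
    reference_srna("bad", "AAAGCACUGAAAACAGUGCU", "...(((((......))))).",
                   stem_loops = list(list(name = "SL1", start = 4, end = 30))),
    "out of bounds"
  )
  # structure pairing bases that cannot pair
  expect_error(
    reference_srna("bad", "AAAAAAAAAAAA", "((......))..", list()),
    "cannot pair"
  )
  tmp <- tempfile(fileext = ".yaml")
  writeLines("name: x\nsequence: ACGU", tmp)
  expect_error(load_reference(tmp), "missing required fields")
})

test_that("variant calling matches substitution sets exactly", {
  wt <- call_variant(ryhb$sequence, ryhb)
  expect_equal(wt$key, "WT")
  expect_length(wt$pos, 0)
  # single A->G at position 30 (DNA input, T/U equivalence)
  read <- ryhb$sequence
  substr(read, 30, 30) <- "G"
  read_dna <- chartr("U", "T", read)
  v <- call_variant(read_dna, ryhb)
  expect_equal(v$key, "A30G")
  # indels and ambiguity are rejected with reason codes
  short <- substr(ryhb$sequence, 1, ryhb$length - 1)
  rej <- call_variant(short, ryhb)
  expect_s3_class(rej, "variant_rejection")
  expect_equal(rej$reason, "length_mismatch")
  ambn <- ryhb$sequence
  substr(ambn, 10, 10) <- "N"
  expect_equal(call_variant(ambn, ryhb)$reason, "ambiguous_base")
  expect_error(call_variant("XYZ", ryhb), "non-nucleotide")
})

test_that("call_variant inverts apply_substitutions on random variants", {
  set.seed(101)
  for (i in 1:40) {
    k <- sample(0:5, 1)
    pos <- sort(sample.int(ryhb$length, k))
    alt <- vapply(pos, function(p) {
      sample(setdiff(c("A", "C", "G", "U"), ryhb$bases[p]), 1)
    }, "")
    v <- variant(pos, alt, ryhb)
    back <- call_variant(apply_substitutions(v, ryhb), ryhb)
    expect_equal(back$key, v$key)
  }
})

test_that("variant construction enforces its invariants", {
  expect_error(variant(c(5, 5), c("G", "C"), ryhb), "duplicate")
  expect_error(variant(30, "A", ryhb), "equals the wild-type")
  expect_error(variant(200, "A", ryhb), "out of range")
  # canonical key is position-sorted regardless of input order
  v <- variant(c(55, 30), c("A", "G"), ryhb)
  expect_equal(v$key, "A30G;U55A")
  expect_equal(parse_variant_key("A30G;U55A", ryhb)$pos, c(30L, 55L))
  expect_error(parse_variant_key("C30G", ryhb), "disagree")
})

test_that("tabulate_bins counts accepted reads and tallies rejections", {
  wt <- ryhb$sequence
  m <- apply_substitutions("A30G", ryhb)
  gates <- sort_gates(c(2, 2.5, 3))
  tbl <- tabulate_bins(list(c(wt, wt, m), c(wt)), ryhb, gates)
  cm <- tbl$counts
  expect_equal(cm$bin1[cm$variant_key == "WT"], 2L)
  expect_equal(cm$bin2[cm$variant_key == "WT"], 1L)
  expect_equal(cm$bin1[cm$variant_key == "A30G"], 1L)
  expect_equal(tbl$rejected, c(0L, 0L))
  # an indel read increments the rejected tally only
  tbl2 <- tabulate_bins(list(c(wt, substr(wt, 2, 94)), c(wt)), ryhb, gates)
  expect_equal(tbl2$rejected, c(1L, 0L))
  expect_equal(sum(tbl2$counts$bin1), 1L)
  # column sums equal accepted reads per bin
  expect_equal(unname(colSums(as.matrix(tbl$counts[c("bin1", "bin2")]))),
               c(3, 1))
  expect_error(tabulate_bins(list(character(0), character(0)), ryhb, gates),
               "no reads")
})

test_that("bin-count TSV round trip is lossless", {
  set.seed(3)
  gates <- sort_gates(seq(2, 3.8, length.out = 7))
  counts <- data.frame(
    variant_key = c("WT", "NOSRNA", "A30G", "U55A"),
    matrix(rpois(24, 40), 4, 6, dimnames = list(NULL, paste0("bin", 1:6)))
  )
  tbl <- bin_count_table(counts, gates, cells_sorted = rpois(6, 5000),
                         reads_sequenced = colSums(counts[, -1]),
                         rejected = rpois(6, 3))
  path <- tempfile(fileext = ".tsv")
  write_bin_counts(tbl, path)
  back <- read_bin_counts(path)
  expect_equal(back$counts, tbl$counts)
  expect_equal(back$gates$boundaries, tbl$gates$boundaries)
  expect_equal(back$cells_sorted, tbl$cells_sorted)
  expect_equal(back$reads_sequenced, tbl$reads_sequenced)
  expect_equal(back$rejected, tbl$rejected)
})

test_that("tabulating simulator-style reads reproduces the emitted counts", {
  set.seed(9)
  keys <- c("WT", "A30G", "A30G;U55A")
  gates <- sort_gates(c(2, 2.5, 3, 3.5))
  cm <- matrix(rpois(9, 8), 3, 3)
  reads <- lapply(1:3, function(b) {
    unlist(lapply(seq_along(keys), function(i) {
      rep(apply_substitutions(keys[i], ryhb), cm[i, b])
    }))
  })
  tbl <- tabulate_bins(reads, ryhb, gates)
  m <- as.matrix(tbl$counts[paste0("bin", 1:3)])
  rownames(m) <- tbl$counts$variant_key
  expect_equal(unname(m[keys, ]), unname(cm))
})
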