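test_that("progressive alignment matches pairwise dynamic programming", {
  al <- progressive_align(c(a = "MKVLIT", b = "MKVLIT"))
  expect_identical(unname(al$rows), c("MKVLIT", "MKVLIT"))  # gapless

  # pairwise scores equal the reference affine-gap implementation
  set.seed(41)
  for (i in 1:10) {
    x <- random_protein(sample(4:10, 1))
    y <- random_protein(sample(4:10, 1))
    ours <- progressive_align(c(a = x, b = y))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(ours$score, Biostrings::score(ref))
  }
  expect_error(progressive_align(c(a = "MKV")), "at least 2")

  # ungapping any row restores its input, also for >2 sequences
  seqs <- setNames(vapply(1:5, function(i) random_protein(60), ""),
                   paste0("s", 1:5))
  al2 <- progressive_align(seqs)
  for (id in names(seqs)) expect_identical(ungap_row(al2, id), seqs[[id]])

  expect_error(as_alignment(c(a = "MK-V", b = "MKV")), "length")
  imp <- as_alignment(c(a = "MK-V", b = "MKVV"))
  expect_equal(imp$source, "imported")
})

test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(p_distance(c(a = "MKVL", b = "MKVL"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "MKVL", b = "MKTI"))["a", "b"], 0.5)
  # brute-force recount oracle
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    len <- sample(20:40, 1)
    rows <- vapply(seq_len(n), function(j) {
      s <- strsplit(random_protein(len), "")[[1]]
      s[sample(len, sample(0:3, 1))] <- "-"
      paste(s, collapse = "")
    }, "")
    names(rows) <- paste0("t", seq_len(n))
    d <- p_distance(rows)
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        ca <- strsplit(rows[a], "")[[1]]; cb <- strsplit(rows[b], "")[[1]]
        diff <- 0; comp <- 0
        for (k in seq_len(len)) {
          if (ca[k] != "-" && cb[k] != "-") {
            comp <- comp + 1
            if (ca[k] != cb[k]) diff <- diff + 1
          }
        }
        expect_equal(d[a, b], diff / comp)
      }
    }
  }
  expect_error(p_distance(c(a = "M-", b = "-K")), "comparable")
})

test_that("neighbor joining is exact on additive distances", {
  # 4-taxon tree with known branch lengths
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(dm)
  expect_equal(sort(tr$tip.label), letters[1:4])
  # recovered split is ab|cd with the generating path lengths
  expect_equal(unname(stats::cophenetic(tr)[letters[1:4], letters[1:4]]),
               unname(dm), tolerance = 1e-8)

  # 3 taxa: closed-form star
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(d3)
  expect_equal(unname(stats::cophenetic(t3)[c("x", "y", "z"), c("x", "y", "z")]),
               unname(d3), tolerance = 1e-8)

  expect_error(
    neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
    "3 taxa")
  bad <- dm; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")

  # random additive trees are recovered exactly (topology and lengths)
  set.seed(43)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    dm <- stats::cophenetic(true)
    est <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_equal(unname(stats::cophenetic(est)[rownames(dm), colnames(dm)]),
                 unname(dm), tolerance = 1e-6)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # every column supports the split ab|cd
  rows <- c(a = strrep("A", 30), b = strrep("A", 30),
            c = strrep("W", 30), d = strrep("W", 30))
  rows <- vapply(names(rows), function(id) {
    # add private variation so distances are distinct
    s <- strsplit(rows[[id]], "")[[1]]
    s[match(id, c("a", "b", "c", "d"))] <- "P"
    paste(s, collapse = "")
  }, "")
  aln <- as_alignment(rows)
  bs <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  expect_true(all(bs$supports == 100))

  bs2 <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  expect_identical(bs$supports, bs2$supports)

  one <- bootstrap_supports(aln, n_reps = 1, seed = 3)
  expect_true(all(one$supports %in% c(0, 100)))
})

test_that("subfamily assignment follows the closest labeled reference", {
  refs <- aqp_reference_set()
  # a reference classifies as itself at 100% identity
  self <- assign_subfamilies(
    setNames(refs$sequence[refs$ref_id == "REF_PIP2"], "q"), refs,
    prefix = "Tst")
  expect_equal(self$subfamily, "PIP")
  expect_equal(self$subgroup, "PIP2")
  expect_equal(self$identity, 100)
  expect_equal(self$assigned_name, "TstPIP2.1")

  # 10% divergence from a PIP2 reference keeps subfamily and subgroup
  set.seed(44)
  cands <- c(
    m1 = mipfam:::.mutate_protein(
      refs$sequence[refs$ref_id == "REF_PIP2"], 0.10,
      tm = aqp_seed_tm_truth("PIP"),
      protected = mipfam:::.seed_protected(mipfam:::.AQP_SEEDS$PIP)),
    far = random_protein(240, alphabet = c("G", "S", "T", "N", "Q", "D"))
  )
  calls <- assign_subfamilies(cands, refs, prefix = "Tst")
  expect_equal(calls$subfamily[calls$gene_id == "m1"], "PIP")
  expect_equal(calls$subgroup[calls$gene_id == "m1"], "PIP2")
  # dissimilar sequence stays unclassified
  expect_false(calls$classified[calls$gene_id == "far"])

  # names are unique within a run
  expect_false(anyDuplicated(na.omit(calls$assigned_name)) > 0)
})
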