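# Position clustering, near matches, convergence, presence matrix.

toy_projection <- function(gene, taxon, family, cols, phases) {
  data.frame(gene_id = gene, ordinal = seq_along(cols), column = cols,
             phase = phases, taxon = taxon, family = family,
             stringsAsFactors = FALSE)
}

test_that("exact clustering partitions by (column, phase)", {
  pr <- rbind(toy_projection("a", "t1", "f", 10, 0),
              toy_projection("b", "t2", "f", 10, 0),
              toy_projection("c", "t3", "f", 10, 0))
  cl <- cluster_introns(pr)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_members, 3L)

  ## same column, different phase: distinct characters
  pr2 <- rbind(toy_projection("a", "t1", "f", 10, 0),
               toy_projection("b", "t2", "f", 10, 1))
  expect_equal(nrow(cluster_introns(pr2)$clusters), 2L)
})

test_that("clustering is a partition (property over random projections)", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    pr <- data.frame(gene_id = paste0("g", seq_len(n)),
                     ordinal = 1L,
                     column = sample(1:15, n, replace = TRUE),
                     phase = sample(0:2, n, replace = TRUE),
                     taxon = paste0("t", seq_len(n)),
                     family = "f")
    cl <- cluster_introns(pr)
    expect_equal(nrow(cl$members), n)                 # nothing lost or duplicated
    expect_equal(sum(cl$clusters$n_members), n)
    ## all members share their cluster's key exactly
    key <- paste(cl$members$column, cl$members$phase)
    ckey <- paste(cl$clusters$column, cl$clusters$phase)
    expect_true(all(key == ckey[match(cl$members$character_id,
                                      cl$clusters$character_id)]))
    ## deterministic ordering by column then phase
    expect_false(is.unsorted(cl$clusters$column))
  }
})

test_that("fixture projections recover the published character inventories", {
  fx <- slc26_fixture()
  cl1 <- cluster_introns(fixture_projections(fx, "slc26a1"))
  expect_equal(nrow(cl1$clusters), 7L)   # A1, E1-E5, O1
  cl2 <- cluster_introns(fixture_projections(fx, "slc26a2"))
  expect_equal(nrow(cl2$clusters), 6L)   # A1p, R1, Q1, O2, N1, N2
})

test_that("near matches report the 7 nt and 23 nt insertion offsets, never merging", {
  fx <- slc26_fixture()
  cl1 <- cluster_introns(fixture_projections(fx, "slc26a1"))
  nm1 <- near_matches(cl1, max_offset_nt = 30)
  expect_equal(nm1$offset_nt, 23L)
  expect_equal(nrow(cl1$clusters), 7L)   # clusters untouched by reporting

  cl2 <- cluster_introns(fixture_projections(fx, "slc26a2"))
  nm2 <- near_matches(cl2, max_offset_nt = 30)
  expect_equal(nm2$offset_nt, 7L)

  ## ceiling is respected; identical positions are one cluster, not a pair
  expect_equal(nrow(near_matches(cl1, max_offset_nt = 10)), 0L)
  pr <- rbind(toy_projection("a", "t1", "f", 10, 0),
              toy_projection("b", "t2", "f", 10, 0))
  expect_equal(nrow(near_matches(cluster_introns(pr))), 0L)
})

test_that("cross-family convergence flags identical and near positions", {
  ## planted shared column/phase across families
  pr <- rbind(toy_projection("a", "t1", "famA", 20, 1),
              toy_projection("b", "t1", "famB", 20, 1))
  cv <- detect_convergence(pr)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$flag, "identical")

  ## planted 6 nt cross-family offset
  pr2 <- rbind(toy_projection("a", "t1", "famA", 20, 1),
               toy_projection("b", "t1", "famB", 22, 1))
  cv2 <- detect_convergence(pr2)
  expect_equal(cv2$offset_nt, 6L)
  expect_equal(cv2$flag, "near")

  ## positions beyond the ceiling, or a single family: empty
  pr3 <- rbind(toy_projection("a", "t1", "famA", 20, 1),
               toy_projection("b", "t1", "famB", 60, 1))
  expect_equal(nrow(detect_convergence(pr3)), 0L)
  expect_equal(nrow(detect_convergence(pr[pr$family == "famA", ])), 0L)
})

test_that("the slc26 fixture shows one identical cross-family site (the ancient intron)", {
  fx <- slc26_fixture()
  cv <- detect_convergence(fixture_projections(fx, "both"))
  ident <- cv[cv$flag == "identical", ]
  expect_equal(nrow(ident), 1L)
  expect_equal(ident$column_a, 132L)
})

test_that("presence matrix cells, zero rows, and paralog rejection", {
  pr <- rbind(toy_projection("a", "t1", "f", 10, 0),
              toy_projection("b", "t2", "f", 10, 0))
  cl <- cluster_introns(pr)
  m <- build_presence_matrix(cl, c(a = "t1", b = "t2", cgene = "t3"))
  expect_equal(unname(rowSums(m)[c("t1", "t2", "t3")]), c(1, 1, 0))

  ## two genes of one family in one taxon must be rejected
  pr_dup <- rbind(toy_projection("a", "t1", "f", 10, 0),
                  toy_projection("b", "t1", "f", 12, 0))
  expect_error(build_presence_matrix(cluster_introns(pr_dup)), "multiple genes")
  ## unmapped gene
  expect_error(build_presence_matrix(cl, c(a = "t1")), "no taxon mapping")

  ## empty projection set with declared taxa: taxa x 0 matrix
  m0 <- build_presence_matrix(cluster_introns(pr[0, ]),
                              c(g1 = "t1", g2 = "t2"))
  expect_equal(dim(m0), c(2L, 0L))
})

test_that("matrix row sums equal per-taxon intron counts and columns have possessors", {
  set.seed(13)
  for (i in 1:5) {
    n_tax <- sample(3:8, 1)
    rows <- list()
    for (t in seq_len(n_tax)) {
      k <- sample(0:5, 1)
      if (k == 0) next
      cols <- sample(1:20, k)
      rows[[length(rows) + 1L]] <-
        toy_projection(paste0("g", t), paste0("t", t), "f", cols,
                       sample(0:2, k, replace = TRUE))
    }
    if (!length(rows)) next
    pr <- do.call(rbind, rows)
    cl <- cluster_introns(pr)
    m <- build_presence_matrix(cl)
    counts <- table(pr$taxon)
    expect_equal(unname(rowSums(m)[names(counts)]), as.vector(counts))
    expect_true(all(colSums(m) >= 1))
  }
})

test_that("matrix round-trips through TSV and writes phylip interop format", {
  fx <- slc26_fixture()
  m <- fx$matrices$slc26a2
  tsv <- tempfile(fileext = ".tsv")
  write_presence_matrix(m, tsv)
  expect_identical(read_presence_matrix(tsv), m)
  phy <- tempfile(fileext = ".phy")
  write_presence_matrix(m, phy, format = "phylip")
  lines <- readLines(phy)
  expect_equal(lines[1], "11 6")
  expect_match(lines[2], "^tetrapod_outgroup 100000$")
})
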