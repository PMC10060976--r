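# Expression container, transforms and file formats.

test_that("log2 transform matches hand values and inverts cleanly", {
  expect_equal(log2_transform(c(0, 3, 1023)), c(0, 2, 10))
  m <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(log2_transform(m), log2(m + 1))

  set.seed(7)
  x <- matrix(rexp(40, 0.1), 8, 5)
  expect_lt(max(abs(log2_transform(2^log2_transform(x) - 1) -
                      log2_transform(x))), 1e-9)

  bad <- matrix(c(1, -2, 3, 4), 2, 2)
  expect_error(log2_transform(bad), "row 2, column 1")
  bad[2, 1] <- NaN
  expect_error(log2_transform(bad), "non-finite")
})

test_that("probe collapse takes geometric means and is order-invariant", {
  x <- matrix(c(2, 8, 5, 1, 1, 1), nrow = 6, ncol = 1,
              dimnames = list(paste0("p", 1:6), "s1"))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G3", p5 = "G3", p6 = "G3")
  out <- collapse_probes(x, map)
  expect_equal(out["G1", 1], 4)      # sqrt(2 * 8)
  expect_equal(out["G2", 1], 5)      # single probe passes through
  expect_equal(out["G3", 1], 1)

  perm <- sample(nrow(x))
  expect_equal(collapse_probes(x[perm, , drop = FALSE], map), out)

  # zero probe among several -> geometric mean 0, not an error
  x0 <- matrix(c(0, 8), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  expect_equal(collapse_probes(x0, map)["G1", 1], 0)

  expect_error(collapse_probes(x, map[-1]), "unmapped probe")
  expect_error(collapse_probes(-x, map), "finite and >= 0")
})

test_that("gene z-scoring standardizes and refuses constant genes", {
  m <- rbind(A = c(1, 2, 3), B = c(0, 1, 5), C = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  sc <- zscore_genes(m, c("A", "B"))
  expect_equal(unname(sc$scaled["A", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(sc$scaled)), c(0, 0))
  expect_equal(unname(apply(sc$scaled, 1, sd)), c(1, 1))
  # idempotence: scaling an already-scaled row changes nothing
  sc2 <- zscore_genes(sc$scaled, c("A", "B"))
  expect_equal(sc2$scaled, sc$scaled, tolerance = 1e-12)
  expect_error(zscore_genes(m, "C"), "constant")
  expect_error(zscore_genes(m, "Z"), "missing")
  # case-insensitive lookup
  expect_equal(zscore_genes(m, "a")$scaled["a", ], sc$scaled["A", ],
               ignore_attr = TRUE)
})

test_that("expression matrix files round-trip bit-identically", {
  set.seed(42)
  m <- matrix(rnorm(12) * 10^runif(12, -3, 3), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  expect_identical(read_expression_matrix(f), m)

  # transposed file with flag
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(t(m), ft, id_column = "sample")
  expect_identical(read_expression_matrix(ft, samples_in_rows = TRUE), m)

  writeLines(c("gene\tS1\tS1", "G1\t1\t2"), f)
  expect_error(read_expression_matrix(f), "duplicated header")
  writeLines(c("gene\tS1\tS2", "G1\t1\t2", "G2\t3"), f)
  expect_error(read_expression_matrix(f), "line 3")
})

test_that("GMT parsing enforces the three-field contract", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tC"), f)
  gs <- read_gmt(f)
  expect_equal(gs$sets, list(S1 = c("A", "B"), S2 = "C"))

  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), f)
  expect_error(read_gmt(f), "duplicate set name")
  writeLines(c("S1\tdesc\tA", "S2\tdesc"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("metabolic model JSON loads, flags empty GPRs, rejects bad rules", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    reactions = list(
      list(id = "R1", gene_reaction_rule = "A and B", subsystem = "S1"),
      list(id = "R2", gene_reaction_rule = "A or C", subsystem = "S2"),
      list(id = "R3", gene_reaction_rule = "", subsystem = "S2")
    ),
    genes = list(list(id = "A"), list(id = "B"), list(id = "C"))
  ), f, auto_unbox = TRUE)
  mod <- read_metabolic_model(f)
  expect_equal(nrow(mod$reactions), 3L)
  expect_equal(mod$reactions$subsystem, c("S1", "S2", "S2"))
  expect_equal(mod$reactions$has_gpr, c(TRUE, TRUE, FALSE))

  f2 <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(mod, f2)
  mod2 <- read_metabolic_model(f2)
  expect_equal(mod2$reactions$gpr, mod$reactions$gpr)
  expect_equal(mod2$genes, mod$genes)

  jsonlite::write_json(list(
    reactions = list(list(id = "R1", gene_reaction_rule = "A and",
                          subsystem = "S1")),
    genes = list(list(id = "A"))
  ), f, auto_unbox = TRUE)
  expect_error(read_metabolic_model(f), "R1")

  jsonlite::write_json(list(
    reactions = list(list(id = "R1", gene_reaction_rule = "A and Z",
                          subsystem = "S1")),
    genes = list(list(id = "A"))
  ), f, auto_unbox = TRUE)
  expect_error(read_metabolic_model(f), "unknown gene")
})

test_that("cohort construction validates metadata and gene symbols", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "tumor")
  co <- expression_cohort("test", m, meta)
  expect_s3_class(co, "expression_cohort")
  expect_equal(dim(co), c(2L, 2L))

  expect_error(expression_cohort("t", m, meta[1, ]), "absent from")
  m2 <- m; rownames(m2) <- c("A", "a")
  expect_error(expression_cohort("t", m2, meta), "case-folding")
  meta_bad <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "tumor",
                             os_event = c(2, 0))
  expect_error(expression_cohort("t", m, meta_bad), "os_event")

  sub <- subset_cohort(co, "s2")
  expect_equal(colnames(sub$values), "s2")
  expect_error(subset_cohort(co, "nope"), "unknown samples")
})
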