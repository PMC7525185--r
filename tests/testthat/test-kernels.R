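test_that("regulatory similarity follows the normalized set-overlap form", {
  expect_equal(regulatory_similarity(c("m1", "m2", "m3"), c("m1", "m2", "m3")), 1)
  expect_equal(regulatory_similarity(c("m1"), c("m2")), 0)
  expect_equal(regulatory_similarity(c("m1", "m2"), c("m1", "m3", "m4")),
               1 / sqrt(6), tolerance = 1e-12)
  expect_equal(regulatory_similarity(character(), c("m1")), 0)
  # literal product form is available but cannot reach 1 for |M| > 1
  expect_equal(regulatory_similarity(c("m1", "m2"), c("m1", "m2"),
                                     form = "product"), 2 / 4)
})

test_that("regulatory kernel matches pairwise scalar computation", {
  study <- tiny_study()
  Y <- study$network$Y
  K <- regulatory_kernel(Y)
  for (pair in list(c(1, 5), c(2, 17), c(9, 9))) {
    mi <- colnames(Y)[Y[pair[1], ] == 1]
    mj <- colnames(Y)[Y[pair[2], ] == 1]
    expect_equal(K[pair[1], pair[2]], regulatory_similarity(mi, mj),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(K, tol = 1e-8))
  expect_true(all(K >= 0 & K <= 1 + 1e-12))
})

test_that("expression similarity is clipped Pearson correlation", {
  x <- c(1, 2, 3)
  expect_equal(expression_similarity(x, x), 1)
  expect_equal(expression_similarity(x, -x), 0)
  # brute-force Pearson via its definition
  y <- c(1, 2, 4)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(expression_similarity(x, y), r, tolerance = 1e-9)
  expect_equal(round(r, 5), 0.98198)
  expect_warning(s <- expression_similarity(c(1, 1, 1), y), "constant")
  expect_equal(s, 0)
})

test_that("GIP kernel matches hand evaluation and is a valid kernel", {
  P <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  K <- gip_kernel(P)
  expect_equal(attr(K, "gamma"), 1)
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(K), rep(1, 2))

  study <- tiny_study()
  K <- gip_kernel(study$network$Y)
  expect_equal(unname(diag(K)), rep(1, 20))
  expect_true(isSymmetric(unname(K), tol = 1e-8))
  expect_true(all(K >= 0 & K <= 1))
  # identical rows score exactly 1
  P2 <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
  expect_equal(gip_kernel(P2)[1, 2], 1)
  # strictly decreasing in Hamming distance, all else equal
  P3 <- rbind(rep(1, 6), c(0, 1, 1, 1, 1, 1), c(0, 0, 1, 1, 1, 1),
              c(0, 0, 0, 1, 1, 1))
  K3 <- gip_kernel(P3)
  expect_true(all(diff(K3[1, 2:4]) < 0))
  expect_error(gip_kernel(matrix(0, 3, 4)), "bandwidth")
})

test_that("semantic values follow the decaying-contribution recursion", {
  dag <- disease_dag(data.frame(parent = "r", child = "d"))
  sv <- semantic_value(dag, "d")
  expect_equal(sort(sv$contributions), sort(c(d = 1, r = 0.5)))
  expect_equal(sv$value, 1.5)
  expect_equal(semantic_value(dag, "r")$value, 1)

  chain <- disease_dag(data.frame(parent = c("root", "a"), child = c("a", "d")))
  expect_equal(semantic_value(chain, "d")$value, 1 + 0.5 + 0.25)
  expect_error(semantic_value(chain, "nope"), "unknown term")
  # contribution takes the max over children when paths differ in length
  diamond <- disease_dag(data.frame(parent = c("r", "r", "a", "b", "c"),
                                    child = c("a", "b", "c", "d", "d")))
  sv <- semantic_value(diamond, "d")
  # r reaches d through b (2 steps) and through a-c (3 steps): max rules
  expect_equal(unname(sv$contributions["r"]), 0.25)
})

test_that("semantic similarity matches hand evaluation on small DAGs", {
  sib <- disease_dag(data.frame(parent = c("r", "r"), child = c("d1", "d2")))
  expect_equal(semantic_similarity(sib, "d1", "d1"), 1)
  expect_equal(semantic_similarity(sib, "d1", "d2"), 1 / 3, tolerance = 1e-12)
  two <- disease_dag(data.frame(parent = c("r1", "r2"), child = c("d1", "d2")))
  expect_equal(semantic_similarity(two, "d1", "d2"), 0)
  # adding a shared ancestor never decreases the score
  deeper <- disease_dag(data.frame(parent = c("top", "r", "r"),
                                   child = c("r", "d1", "d2")))
  expect_gte(semantic_similarity(deeper, "d1", "d2"),
             semantic_similarity(sib, "d1", "d2"))
})

test_that("semantic kernel has unit diagonal and is symmetric", {
  study <- tiny_study()
  K <- semantic_kernel(study$dag, study$network$disease$ids)
  expect_equal(unname(diag(K)), rep(1, 8))
  expect_true(isSymmetric(unname(K), tol = 1e-8))
  expect_true(all(K >= 0 & K <= 1))
})

test_that("kernel stacks assemble with graceful degradation", {
  study <- tiny_study()
  stacks <- suppressMessages(assemble_kernel_stacks(
    study$network, study$expression, study$sequences, study$dag,
    study$precomputed))
  expect_named(stacks$circ, c("SC_Seq", "SC_RG", "SC_EP", "SC_GIP"))
  expect_named(stacks$disease, c("SD_Dss", "SD_GIP", "SD_pre1", "SD_pre2"))
  for (K in c(stacks$circ, stacks$disease)) {
    expect_true(all(is.finite(K)))
    expect_true(isSymmetric(unname(K), tol = 1e-8))
    expect_true(all(K >= 0 & K <= 1 + 1e-12))
  }
  # no expression input: kernel dropped with a message
  stacks3 <- suppressMessages(assemble_kernel_stacks(
    study$network, NULL, study$sequences, study$dag, study$precomputed))
  expect_equal(length(stacks3$circ), 3)
  # fewer than two kernels on a side is a configuration error
  expect_error(
    suppressMessages(assemble_kernel_stacks(
      study$network, NULL, NULL, NULL, list())),
    "at least 2 kernels")
})
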