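make_toy_context <- function(nc = 5, nd = 3, nm = 4, np = 2, seed = 31) {
  set.seed(seed)
  circ <- sprintf("c%d", 1:nc); dis <- sprintf("d%d", 1:nd)
  mir <- sprintf("m%d", 1:nm)
  A <- matrix(rbinom(nc * nd, 1, 0.4), nc, nd, dimnames = list(circ, dis))
  Y <- matrix(rbinom(nc * nm, 1, 0.5), nc, nm, dimnames = list(circ, mir))
  O <- matrix(rbinom(nd * nm, 1, 0.5), nd, nm, dimnames = list(dis, mir))
  Y[rowSums(Y) == 0, 1] <- 1L; O[rowSums(O) == 0, 1] <- 1L
  edges <- function(M) {
    w <- which(M == 1, arr.ind = TRUE)
    data.frame(id_a = rownames(M)[w[, 1]], id_b = colnames(M)[w[, 2]])
  }
  nw <- build_network(edges(A), edges(Y), edges(O))
  Sc <- generate_random_kernels(nc, 2, seed)[[1]]
  Sd <- generate_random_kernels(nd, 2, seed + 1)[[1]]
  dimnames(Sc) <- list(nw$circ$ids, nw$circ$ids)
  dimnames(Sd) <- list(nw$disease$ids, nw$disease$ids)
  proj <- fit_mirna_projector(nw$Y, nw$O, np = np)
  list(nw = nw, Sc = Sc, Sd = Sd, proj = proj)
}

test_that("the miRNA projector is an orthonormal centred PCA", {
  study <- tiny_study()
  nw <- study$network
  proj <- fit_mirna_projector(nw$Y, nw$O, np = 5)
  expect_equal(crossprod(proj$rotation), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # successive component variances are non-increasing
  expect_true(all(diff(proj$sdev) <= 1e-12))
  scores <- project_profile(proj, rbind(nw$Y, nw$O))
  expect_equal(unname(apply(scores, 2, var)), proj$sdev^2, tolerance = 1e-9)
  expect_error(fit_mirna_projector(nw$Y, nw$O, np = 40), "np")
})

test_that("exact low-rank profiles are reconstructed with matching np", {
  base <- rbind(c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1))
  Y <- base[c(1, 2, 1, 1), ]; O <- base[c(2, 2, 1), ]
  rownames(Y) <- sprintf("c%d", 1:4); rownames(O) <- sprintf("d%d", 1:3)
  proj <- fit_mirna_projector(Y, O, np = 1)  # centred stack has rank 1
  scores <- project_profile(proj, rbind(Y, O))
  recon <- scores %*% t(proj$rotation) +
    matrix(proj$center, nrow(scores), ncol(Y), byrow = TRUE)
  expect_equal(unname(recon), unname(rbind(Y, O)), tolerance = 1e-10)
})

test_that("pair features match the cell-by-cell assembly oracle", {
  ctx <- make_toy_context()
  nw <- ctx$nw
  Yp <- project_profile(ctx$proj, nw$Y)
  Op <- project_profile(ctx$proj, nw$O)
  for (mask in c(TRUE, FALSE)) {
    for (pair in list(c(1, 1), c(2, 3), c(5, 2))) {
      i <- pair[1]; j <- pair[2]
      X <- build_pair_feature(nw$circ$ids[i], nw$disease$ids[j],
                              ctx$Sc, ctx$Sd, nw, ctx$proj,
                              mask_label = mask)
      expect_equal(unname(X),
                   oracle_pair_feature(i, j, ctx$Sc, ctx$Sd, nw$A, Yp, Op,
                                       mask),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(attr(X, "blocks"), c(nc = 5, nd = 3, np = 2))
    }
  }
})

test_that("masking removes the pair's own label from its feature", {
  ctx <- make_toy_context()
  nw <- ctx$nw
  pos <- which(nw$A == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(pos))) {
    i <- pos[r, 1]; j <- pos[r, 2]
    X <- build_pair_feature(nw$circ$ids[i], nw$disease$ids[j],
                            ctx$Sc, ctx$Sd, nw, ctx$proj, mask_label = TRUE)
    expect_equal(X[2, i], 0)        # block 1, associations of d_j
    expect_equal(X[1, 5 + j], 0)    # block 2, associations of c_i
    Xu <- build_pair_feature(nw$circ$ids[i], nw$disease$ids[j],
                             ctx$Sc, ctx$Sd, nw, ctx$proj, mask_label = FALSE)
    expect_equal(Xu[2, i], 1)
  }
})

test_that("datasets stack features with stable width and reject duplicates", {
  ctx <- make_toy_context()
  nw <- ctx$nw
  pairs <- data.frame(circ = c("c1", "c2", "c3"),
                      disease = c("d1", "d1", "d2"),
                      label = c(1L, 0L, NA))
  ds <- build_dataset(pairs, ctx$Sc, ctx$Sd, nw, ctx$proj)
  expect_equal(dim(ds$X), c(3, 2, 5 + 3 + 2))
  expect_true(all(is.finite(ds$X)))
  expect_error(build_dataset(pairs[c(1, 1), ], ctx$Sc, ctx$Sd, nw, ctx$proj),
               "duplicate")
  expect_equal(nrow(build_dataset(pairs[0, ], ctx$Sc, ctx$Sd, nw,
                                  ctx$proj)$pairs), 0)
  expect_error(build_dataset(data.frame(circ = "cX", disease = "d1"),
                             ctx$Sc, ctx$Sd, nw, ctx$proj), "unknown")
})
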